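## Submission and gold-standard file I/O.
##
## Dialect: UTF-8, tab-separated, no header; lines starting with '#' and
## blank lines are ignored. Writers mirror readers bit-exactly for files in
## canonical form.

readLinesKeep <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

stopAtLine <- function(lineno, ...) {
  stop("line ", lineno, ": ", ..., call. = FALSE)
}

#' Read a submission run
#'
#' Parses a tab-separated submission file with one prediction per line:
#' \code{document_id <TAB> identifier <TAB> rank <TAB> confidence}.
#' In strict mode, within-document ranks must be exactly 1..n with no gaps
#' and no (document, identifier) pair may repeat; violations are reported
#' with their line number. In non-strict mode duplicate pairs are collapsed
#' keeping the highest confidence, and ranks are renumbered canonically
#' (confidence descending, ties by submitted rank then identifier).
#'
#' @param path Path to the submission file.
#' @param runId Run id to attach; defaults to the file name without
#'   extension.
#' @param strict Enforce rank and duplicate invariants verbatim.
#' @return A [SourceRun-class].
#' @seealso [writeSubmission()]
#' @export
readSubmission <- function(path, runId = sub("\\.[^.]*$", "", basename(path)),
                           strict = FALSE) {
  lk <- readLinesKeep(path)
  fields <- strsplit(lk$lines, "\t", fixed = TRUE)
  n <- length(fields)
  if (!n) {
    return(newSourceRun(runId, data.frame(document_id = character(),
                                          identifier = character(),
                                          rank = integer(),
                                          confidence = numeric())))
  }
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stopAtLine(lk$lineno[bad[1]], "expected 4 tab-separated fields, got ",
               lengths(fields)[bad[1]])
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  doc <- m[, 1]; ident <- m[, 2]
  rnk <- suppressWarnings(as.integer(m[, 3]))
  conf <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(rnk))
    stopAtLine(lk$lineno[which(is.na(rnk))[1]], "non-integer rank '",
               m[is.na(rnk), 3][1], "'")
  if (anyNA(conf) || any(!is.finite(conf)))
    stopAtLine(lk$lineno[which(is.na(conf) | !is.finite(conf))[1]],
               "non-numeric confidence '", m[which(is.na(conf) | !is.finite(conf))[1], 4], "'")
  if (any(!nzchar(doc)) || any(!nzchar(ident)))
    stopAtLine(lk$lineno[which(!nzchar(doc) | !nzchar(ident))[1]],
               "empty document id or identifier")

  if (strict) {
    key <- objectKey(doc, ident)
    if (anyDuplicated(key))
      stopAtLine(lk$lineno[which(duplicated(key))[1]],
                 "duplicate (document, identifier) pair in strict mode")
    for (d in unique(doc)) {
      i <- which(doc == d)
      r <- sort(rnk[i])
      exp <- seq_along(i)
      if (!identical(as.integer(r), exp)) {
        off <- which(r != exp[seq_along(r)])[1]
        stopAtLine(lk$lineno[i[order(rnk[i])][off]],
                   "rank gap in document ", d, ": expected rank ", exp[off],
                   ", found ", r[off])
      }
    }
    p <- data.frame(document_id = doc, identifier = ident, rank = rnk,
                    confidence = conf, stringsAsFactors = FALSE)
    o <- order(p$document_id, p$rank, method = "radix")
    return(newSourceRun(runId, p[o, ], canonicalize = FALSE))
  }

  p <- data.frame(document_id = doc, identifier = ident, rank = rnk,
                  confidence = conf, stringsAsFactors = FALSE)
  ## collapse duplicates keeping highest confidence (then best rank)
  o <- order(p$document_id, p$identifier, -p$confidence, p$rank, method = "radix")
  p <- p[o, ]
  p <- p[!duplicated(objectKey(p$document_id, p$identifier)), ]
  newSourceRun(runId, p, canonicalize = TRUE)
}

formatConfidence <- function(x) {
  ## format each value independently so a vector containing e.g. 1 and 0.9
  ## writes "1" and "0.9", not a common-width "1.0"/"0.9"
  vapply(x, format, character(1), trim = TRUE, scientific = FALSE,
         digits = 15)
}

#' Write a submission run
#'
#' Writes the canonical tab-separated representation; reading the result
#' back with [readSubmission()] reproduces the run exactly, and for a file
#' already in canonical form write(read(file)) is byte-identical.
#'
#' @param run A [SourceRun-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSubmission <- function(run, path) {
  p <- predictions(run)
  o <- order(p$document_id, p$rank, method = "radix")
  p <- p[o, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%d\t%s", p$document_id, p$identifier, p$rank,
                   formatConfidence(p$confidence))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gold standard
#'
#' Parses a tab-separated annotation file: \code{document_id <TAB>
#' identifier}, one annotation per line. A line holding only a document id
#' declares a document with an empty annotation set. Duplicate annotations
#' are collapsed silently (set semantics).
#'
#' @param path Path to the annotation file.
#' @return A [GoldStandard-class].
#' @seealso [writeGold()]
#' @export
readGold <- function(path) {
  lk <- readLinesKeep(path)
  if (!length(lk$lines)) return(newGoldStandard())
  trailing <- which(endsWith(lk$lines, "\t"))
  if (length(trailing))
    stopAtLine(lk$lineno[trailing[1]], "empty identifier token")
  fields <- strsplit(lk$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) > 2L | lengths(fields) < 1L)
  if (length(bad))
    stopAtLine(lk$lineno[bad[1]], "expected 1 or 2 tab-separated fields")
  ann <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (!nzchar(f[1])) stopAtLine(lk$lineno[i], "empty document id")
    if (length(f) == 2L && !nzchar(f[2]))
      stopAtLine(lk$lineno[i], "empty identifier token")
    cur <- ann[[f[1]]]
    if (is.null(cur)) cur <- character()
    if (length(f) == 2L) cur <- c(cur, f[2])
    ann[[f[1]]] <- cur
  }
  newGoldStandard(ann)
}

#' Write a gold standard
#'
#' @param gold A [GoldStandard-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGold <- function(gold, path) {
  a <- annotations(gold)
  lines <- unlist(lapply(names(a), function(d) {
    if (length(a[[d]])) paste(d, a[[d]], sep = "\t") else d
  }), use.names = FALSE)
  writeLines(if (is.null(lines)) character() else lines, path, useBytes = TRUE)
  invisible(path)
}
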