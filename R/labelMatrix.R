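#' Build the binary label matrix from submission runs
#'
#' Treats each run as a labelling source and each (document, identifier)
#' pair returned by any source as an object to be labelled. The resulting
#' indicator matrix has entry 1 where a source returned the pair and 0
#' otherwise. Objects are ordered lexicographically by document id then
#' identifier; sources keep their input order, so the construction is
#' deterministic and permutation of the runs only permutes columns.
#'
#' @param runs Non-empty list of [SourceRun-class] objects with distinct
#'   run ids.
#' @param documents Optional character vector restricting predictions to
#'   these document ids.
#' @return A [LabelMatrix-class].
#' @examples
#' a <- newSourceRun("A", data.frame(document_id = "D1", identifier = "G1",
#'                                   confidence = 1))
#' b <- newSourceRun("B", data.frame(document_id = "D1",
#'                                   identifier = c("G1", "G2"),
#'                                   confidence = c(1, 0.5)))
#' deltaMatrix(buildLabelMatrix(list(a, b)))
#' @export
buildLabelMatrix <- function(runs, documents = NULL) {
  if (!length(runs)) stop("'runs' must be a non-empty list of SourceRun objects")
  ids <- vapply(runs, runId, character(1))
  if (anyDuplicated(ids)) stop("run ids must be distinct")
  preds <- lapply(runs, function(r) {
    p <- predictions(r)
    if (!is.null(documents)) p <- p[p$document_id %in% documents, , drop = FALSE]
    p
  })
  allp <- do.call(rbind, preds)
  if (!nrow(allp)) stop("zero objects after document restriction")
  key <- objectKey(allp$document_id, allp$identifier)
  ukey <- unique(key)
  first <- !duplicated(key)
  obj <- data.frame(document_id = allp$document_id[first],
                    identifier = allp$identifier[first],
                    stringsAsFactors = FALSE)
  o <- order(obj$document_id, obj$identifier, method = "radix")
  obj <- obj[o, , drop = FALSE]
  rownames(obj) <- NULL
  okey <- objectKey(obj$document_id, obj$identifier)
  delta <- matrix(0L, nrow(obj), length(runs),
                  dimnames = list(NULL, ids))
  offset <- 0L
  for (i in seq_along(preds)) {
    ni <- nrow(preds[[i]])
    if (ni) {
      j <- match(key[(offset + 1L):(offset + ni)], okey)
      delta[j, i] <- 1L
    }
    offset <- offset + ni
  }
  methods::new("LabelMatrix", objects = obj, sources = ids, delta = delta)
}

#' Density of a label matrix
#'
#' Fraction of 1 entries: total predictions divided by N x M.
#'
#' @param matrix A [LabelMatrix-class].
#' @return A single number in (0, 1].
#' @export
labelDensity <- function(matrix) mean(deltaMatrix(matrix))
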