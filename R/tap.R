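## Threshold Average Precision (TAP-k).
##
## For a query (document) with P gold positives and a ranked list cut off at
## score threshold x:
##   APC_x  = sum over gold-hit ranks with score >= x of precision-at-rank, / P
##   P_x    = precision at the last rank with score >= x (0 if none retrieved)
##   APCP_x = (P * APC_x + P_x) / (P + 1)
## The terminal precision penalizes keeping uninformative tails below the
## last true positive. TAP-k averages APCP_x over queries, with x the
## largest score at which the median per-query false-positive count
## reaches k.

#' Average precision of a ranked list
#'
#' Sum of precision at each rank holding a gold item, divided by the number
#' of gold positives.
#'
#' @param ranked Character vector of identifiers in rank order (or a
#'   data.frame with an \code{identifier} column ordered by rank).
#' @param gold Character vector: the gold identifier set (non-empty).
#' @return Average precision in [0, 1].
#' @examples
#' averagePrecision(c("A", "X", "B"), c("A", "B"))  # (1 + 2/3)/2
#' @export
averagePrecision <- function(ranked, gold) {
  if (is.data.frame(ranked)) ranked <- ranked$identifier
  if (!length(gold)) stop("gold set must be non-empty; see apcpAtThreshold for the P = 0 policy")
  if (!length(ranked)) return(0)
  tp <- ranked %in% gold
  sum((cumsum(tp) / seq_along(tp))[tp]) / length(unique(gold))
}

## workhorse: identifiers/confidences in rank order (confidence non-increasing)
apcpOne <- function(identifier, confidence, gold, x) {
  P <- length(gold)
  nret <- sum(confidence >= x)
  if (P == 0L) {
    return(list(P = 0L, apc = 0, terminalPrecision = 0,
                apcp = as.numeric(nret == 0L), nFalsePositives = nret))
  }
  if (nret == 0L)
    return(list(P = P, apc = 0, terminalPrecision = 0, apcp = 0,
                nFalsePositives = 0L))
  tp <- identifier[seq_len(nret)] %in% gold
  prec <- cumsum(tp) / seq_len(nret)
  apc <- sum(prec[tp]) / P
  px <- prec[nret]
  list(P = P, apc = apc, terminalPrecision = px,
       apcp = (P * apc + px) / (P + 1),
       nFalsePositives = nret - sum(tp))
}

#' Average precision with cutoff and terminal penalty for one query
#'
#' Evaluates APC_x, the terminal precision P_x, and their weighted average
#' APCP_x = (P * APC_x + P_x) / (P + 1) for a single query at score cutoff
#' \code{x}. For queries with no gold positives (P = 0), APCP_x is 1 when
#' nothing is retrieved at the cutoff and 0 otherwise, rewarding abstention.
#'
#' @param ranked data.frame with columns \code{identifier} and
#'   \code{confidence}, ordered by rank (confidence non-increasing), e.g.
#'   one document's rows of [predictions()].
#' @param gold Character vector of gold identifiers for the query (may be
#'   empty).
#' @param x Score threshold; items with confidence >= x are retrieved.
#' @return One-row data.frame with columns \code{P}, \code{apc},
#'   \code{terminalPrecision}, \code{apcp}, \code{nFalsePositives}.
#' @export
apcpAtThreshold <- function(ranked, gold, x) {
  stopifnot(is.data.frame(ranked),
            all(c("identifier", "confidence") %in% names(ranked)))
  as.data.frame(apcpOne(ranked$identifier, ranked$confidence,
                        unique(gold), x))
}

## Per-document prediction splits for the documents of a gold standard.
## Documents absent from the run get empty entries.
splitByGoldDoc <- function(run, gold) {
  docs <- names(annotations(gold))
  p <- predictions(run)
  p <- p[p$document_id %in% docs, , drop = FALSE]
  idx <- split(seq_len(nrow(p)), factor(p$document_id, levels = docs))
  lapply(idx, function(i) list(identifier = p$identifier[i],
                               confidence = p$confidence[i]))
}

#' Select the TAP-k score threshold
#'
#' Scans the candidate thresholds (the distinct submitted confidence
#' scores, in descending order) and returns the largest score x at which
#' the median per-query false-positive count over all gold documents
#' reaches k. Queries with no submission retrieve nothing at any threshold
#' and enter the median with 0 false positives. If no candidate reaches a
#' median of k, the retrieve-all sentinel \code{-Inf} is returned.
#'
#' @param run A [SourceRun-class].
#' @param gold A [GoldStandard-class] defining the queries.
#' @param k Tolerated median number of false positives (>= 1).
#' @return The threshold (a score, or \code{-Inf} for retrieve-all).
#' @export
selectThresholdForK <- function(run, gold, k) {
  stopifnot(k >= 1)
  docs <- names(annotations(gold))
  if (!length(docs)) stop("gold standard has no documents")
  per <- splitByGoldDoc(run, gold)
  cand <- sort(unique(unlist(lapply(per, `[[`, "confidence"), use.names = FALSE)),
               decreasing = TRUE)
  if (!length(cand)) return(-Inf)
  ann <- annotations(gold)
  ## false-positive count step functions, evaluated at every candidate
  fpmat <- vapply(docs, function(d) {
    conf <- per[[d]]$confidence
    if (!length(conf)) return(numeric(length(cand)))
    fp <- cumsum(!(per[[d]]$identifier %in% ann[[d]]))
    asc <- rev(conf)                       # ascending
    nret <- length(conf) - findInterval(cand, asc, left.open = TRUE)
    c(0, fp)[nret + 1L]
  }, numeric(length(cand)))
  med <- if (is.matrix(fpmat)) apply(fpmat, 1L, stats::median) else stats::median(fpmat)
  hit <- which(med >= k)
  if (!length(hit)) -Inf else cand[hit[1L]]
}

#' TAP-k score of a run
#'
#' Selects the score threshold via [selectThresholdForK()], evaluates
#' APCP_x for every gold document via [apcpAtThreshold()], and averages.
#' Documents absent from the run contribute an empty ranked list.
#'
#' @param run A [SourceRun-class].
#' @param gold A [GoldStandard-class]; its documents are the queries.
#' @param k Tolerated median number of false positives.
#' @param zeroGoldPolicy How to treat queries with no gold positives:
#'   \code{"score"} (default) scores them 1 on abstention and 0 otherwise;
#'   \code{"exclude"} drops them from the average.
#' @return A [TapResult-class].
#' @examples
#' run <- newSourceRun("r", data.frame(document_id = "D1",
#'                                     identifier = c("G1", "G2"),
#'                                     confidence = c(0.9, 0.4)))
#' gold <- newGoldStandard(list(D1 = c("G1", "G2")))
#' tapScore(tapKScore(run, gold, k = 5))  # perfect retrieval -> 1
#' @export
tapKScore <- function(run, gold, k, zeroGoldPolicy = c("score", "exclude")) {
  zeroGoldPolicy <- match.arg(zeroGoldPolicy)
  ann <- annotations(gold)
  if (!length(ann)) stop("gold standard is empty")
  x <- selectThresholdForK(run, gold, k)
  per <- splitByGoldDoc(run, gold)
  rows <- lapply(names(ann), function(d) {
    e <- apcpOne(per[[d]]$identifier, per[[d]]$confidence,
                 unique(ann[[d]]), x)
    cbind(data.frame(document_id = d, stringsAsFactors = FALSE),
          as.data.frame(e))
  })
  pq <- do.call(rbind, rows)
  rownames(pq) <- NULL
  use <- if (zeroGoldPolicy == "exclude") pq$P > 0 else rep(TRUE, nrow(pq))
  if (!any(use)) stop("no queries left to average after excluding P = 0 queries")
  methods::new("TapResult", k = as.integer(k), thresholdX = x,
               perQuery = pq, tap = mean(pq$apcp[use]))
}
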