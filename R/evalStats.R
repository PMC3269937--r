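## Set-overlap metrics, pooled break-even point, score-table correlation,
## and paired Wilcoxon comparison of runs.

#' Precision, recall and F1 from overlap counts
#'
#' @param nGold Number of gold-positive labels.
#' @param nPred Number of predicted-positive labels.
#' @param nOverlap Number of labels in both (must not exceed either count).
#' @return Named numeric vector \code{c(precision, recall, f1)}; any 0/0 is
#'   defined as 0.
#' @examples
#' precisionRecallF1(1667, 1813, 528)  # ~ (0.29, 0.32, 0.30)
#' @export
precisionRecallF1 <- function(nGold, nPred, nOverlap) {
  if (nOverlap > min(nGold, nPred))
    stop("overlap cannot exceed either margin")
  safeDiv <- function(a, b) if (b == 0) 0 else a / b
  precision <- safeDiv(nOverlap, nPred)
  recall <- safeDiv(nOverlap, nGold)
  f1 <- safeDiv(2 * precision * recall, precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Precision/recall/F1 of one annotation set against another
#'
#' Convenience wrapper counting per-document positive labels in
#' \code{pred} vs \code{gold} over the documents of \code{gold}.
#'
#' @param gold,pred [GoldStandard-class] objects (pred may be a silver
#'   standard).
#' @return As [precisionRecallF1()].
#' @export
annotationOverlap <- function(gold, pred) {
  ga <- annotations(gold)
  pa <- annotations(pred)
  nGold <- sum(lengths(ga))
  nPred <- sum(lengths(pa[names(pa) %in% names(ga)]))
  nOverlap <- sum(vapply(names(ga), function(d)
    length(intersect(ga[[d]], pa[[d]])), numeric(1)))
  precisionRecallF1(nGold, nPred, nOverlap)
}

#' Pooled break-even point of a run
#'
#' Pools all predictions over the gold documents, orders them by confidence
#' descending (ties broken by document, submitted rank, then identifier),
#' and returns the precision at the rank equal to the total number of gold
#' positives (R-precision), where precision equals recall by construction.
#' If the run returns fewer predictions than there are gold positives, the
#' value is total true positives over gold positives. Invariant under
#' monotone transforms of the confidences.
#'
#' @param run A [SourceRun-class].
#' @param gold A [GoldStandard-class] with at least one positive overall.
#' @return The break-even precision in [0, 1].
#' @export
breakevenPoint <- function(run, gold) {
  ann <- annotations(gold)
  G <- sum(lengths(ann))
  if (G == 0) stop("gold standard has no positives")
  p <- predictions(run)
  p <- p[p$document_id %in% names(ann), , drop = FALSE]
  if (!nrow(p)) return(0)
  o <- order(-p$confidence, p$document_id, p$rank, p$identifier,
             method = "radix")
  p <- p[o, , drop = FALSE]
  tp <- mapply(function(d, g) g %in% ann[[d]], p$document_id, p$identifier,
               USE.NAMES = FALSE)
  sum(tp[seq_len(min(G, nrow(p)))]) / G
}

#' Pearson correlation between score vectors
#'
#' Standard product-moment correlation with input validation (equal length
#' >= 2, both vectors non-constant), as used to compare TAP score columns
#' across evaluation standards.
#'
#' @param xs,ys Numeric vectors.
#' @return The correlation coefficient.
#' @export
pearsonCorrelation <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("vectors must have equal length")
  if (length(xs) < 2L) stop("need at least 2 observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation is undefined for a constant vector")
  stats::cor(xs, ys)
}

#' Paired Wilcoxon signed-rank comparison of per-query scores
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences of two
#' per-query score vectors (e.g. APCP values of two runs over the same
#' queries). Zero differences are dropped; the exact null distribution is
#' used for n <= 25 remaining pairs without ties in |difference|, otherwise
#' the normal approximation with continuity correction.
#'
#' @param a,b Numeric vectors over identical query sets.
#' @return List with \code{statistic} (V), \code{p.value},
#'   \code{n} (non-zero differences), \code{exact}, and \code{degenerate}
#'   (TRUE when all differences are zero, in which case p = 1).
#' @export
wilcoxonCompare <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p.value = 1, n = 0L, exact = TRUE,
                degenerate = TRUE))
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25L && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                            mu = 0, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, n = n,
       exact = exact, degenerate = FALSE)
}
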