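## Latent-class EM over M binary labelling sources (Dawid-Skene /
## Hui-Walter family, two classes, conditional independence).
##
## M-step (Laplace smoothed, equivalently MAP under Beta(2,2)):
##   as_i = (sum_j delta_ij p_j + 1) / (sum_j p_j + 2)
##   bs_i = (sum_j (1-delta_ij)(1-p_j) + 1) / (sum_j (1-p_j) + 2)
## E-step (Bayes, computed in log space):
##   p_j = pr A_j / (pr A_j + (1-pr) B_j)
##   A_j = prod_i as_i^delta_ij (1-as_i)^(1-delta_ij)
##   B_j = prod_i (1-bs_i)^delta_ij bs_i^(1-delta_ij)

#' Initial truth probabilities
#'
#' Initializes each object's probability of being correct to the fraction
#' of the M source labels that are positive.
#'
#' @param matrix A [LabelMatrix-class].
#' @return Numeric vector of length N.
#' @export
initializeProbabilities <- function(matrix) {
  d <- deltaMatrix(matrix)
  rowSums(d) / ncol(d)
}

#' EM maximization step
#'
#' Laplace-smoothed sensitivity and specificity estimates for every source
#' given current truth probabilities. Smoothing keeps all estimates
#' strictly inside (0,1), so no degenerate configuration exists.
#'
#' @param matrix A [LabelMatrix-class].
#' @param p Numeric vector in [0,1], one probability per object.
#' @return data.frame with columns \code{run_id}, \code{sensitivity},
#'   \code{specificity}.
#' @export
mStep <- function(matrix, p) {
  d <- deltaMatrix(matrix)
  stopifnot(length(p) == nrow(d), all(p >= 0 & p <= 1))
  as_i <- (drop(crossprod(d, p)) + 1) / (sum(p) + 2)
  bs_i <- (drop(crossprod(1 - d, 1 - p)) + 1) / (sum(1 - p) + 2)
  data.frame(run_id = sources(matrix), sensitivity = as_i,
             specificity = bs_i, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' EM expectation step
#'
#' Posterior probability that each object is correct given the source
#' labels, the current source profiles and a uniform prior, by Bayes'
#' theorem. Likelihood products are accumulated in log space.
#'
#' @param matrix A [LabelMatrix-class].
#' @param profiles data.frame as returned by [mStep()].
#' @param prior Prior probability in (0,1) that an object is correct.
#' @return Numeric vector of posterior probabilities.
#' @export
eStep <- function(matrix, profiles, prior) {
  stopifnot(prior > 0, prior < 1)
  d <- deltaMatrix(matrix)
  as_i <- profiles$sensitivity
  bs_i <- profiles$specificity
  logA <- drop(d %*% log(as_i) + (1 - d) %*% log1p(-as_i))
  logB <- drop(d %*% log1p(-bs_i) + (1 - d) %*% log(bs_i))
  ## p = 1 / (1 + exp(logitPriorComplement + logB - logA))
  stats::plogis(log(prior) - log1p(-prior) + logA - logB)
}

## penalized observed-data log posterior at given profiles
emObjective <- function(matrix, profiles, prior) {
  d <- deltaMatrix(matrix)
  as_i <- profiles$sensitivity
  bs_i <- profiles$specificity
  la <- log(prior) + drop(d %*% log(as_i) + (1 - d) %*% log1p(-as_i))
  lb <- log1p(-prior) + drop(d %*% log1p(-bs_i) + (1 - d) %*% log(bs_i))
  m <- pmax(la, lb)
  sum(m + log(exp(la - m) + exp(lb - m))) +
    sum(stats::dbeta(as_i, 2, 2, log = TRUE)) +
    sum(stats::dbeta(bs_i, 2, 2, log = TRUE))
}

#' Run the EM consensus algorithm
#'
#' Alternates [mStep()] and [eStep()] from the label-fraction
#' initialization until the maximum absolute change in any probability
#' falls below \code{tol}, or \code{maxIter} iterations. The penalized
#' log-posterior (marginal log-likelihood plus a Beta(2,2) log-prior on
#' each sensitivity and specificity, the prior implied by the Laplace
#' smoothing) is recorded each iteration and is non-decreasing up to
#' numerical tolerance.
#'
#' @param matrix A [LabelMatrix-class].
#' @param prior Uniform prior probability that an object is correct. Use
#'   0.5 when selecting discriminative documents; use the expected fraction
#'   of correct ids (0.01 in the benchmark this package models) when
#'   inferring a silver standard.
#' @param tol Convergence tolerance on max |change in p|.
#' @param maxIter Iteration cap; non-convergence yields a warning, not an
#'   error.
#' @return A [ConsensusResult-class].
#' @export
runEM <- function(matrix, prior, tol = 1e-8, maxIter = 1000L) {
  stopifnot(prior > 0, prior < 1)
  p <- initializeProbabilities(matrix)
  trace <- numeric()
  converged <- FALSE
  iter <- 0L
  profiles <- NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    profiles <- mStep(matrix, p)
    trace[iter] <- emObjective(matrix, profiles, prior)
    pNew <- eStep(matrix, profiles, prior)
    delta <- max(abs(pNew - p))
    p <- pNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", maxIter, " iterations")
  methods::new("ConsensusResult", p = p, profiles = profiles, prior = prior,
               iterations = iter, converged = converged,
               objectiveTrace = trace)
}

#' Extract the silver standard from a consensus result
#'
#' Accepts as correct every object whose posterior probability reaches the
#' threshold (boundary included: p = threshold is accepted) and returns the
#' per-document identifier sets in [GoldStandard-class] shape. Every
#' document present in the label matrix appears, with an empty set when no
#' object passes.
#'
#' @param result A [ConsensusResult-class].
#' @param matrix The [LabelMatrix-class] the result was computed from.
#' @param threshold Acceptance threshold on p (default 0.5).
#' @return A [GoldStandard-class] holding the consensus annotations.
#' @export
extractSilverStandard <- function(result, matrix, threshold = 0.5) {
  p <- probabilities(result)
  obj <- labelObjects(matrix)
  if (length(p) != nrow(obj))
    stop("result is not aligned with the label matrix")
  keep <- p >= threshold
  ann <- split(obj$identifier[keep],
               factor(obj$document_id[keep], levels = unique(obj$document_id)))
  newGoldStandard(ann)
}

#' Binary label entropy
#'
#' Shannon entropy, in nats, of a Bernoulli(p) label:
#' -p log p - (1-p) log(1-p), with 0 log 0 = 0.
#'
#' @param p Probability (vectorized), in [0,1].
#' @return Entropy value(s) in [0, log 2].
#' @export
labelEntropy <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]")
  h <- numeric(length(p))
  i <- p > 0 & p < 1
  h[i] <- -p[i] * log(p[i]) - (1 - p[i]) * log1p(-p[i])
  h
}

#' Entropy score per document
#'
#' Scores each document by the sum of the label entropies of its objects:
#' high scores mark documents whose gene ids the sources report most
#' variably, i.e. the most discriminative documents to annotate.
#'
#' @param result A [ConsensusResult-class].
#' @param matrix The aligned [LabelMatrix-class].
#' @return Named numeric vector of per-document entropy sums.
#' @export
scoreDocuments <- function(result, matrix) {
  p <- probabilities(result)
  obj <- labelObjects(matrix)
  if (length(p) != nrow(obj))
    stop("result is not aligned with the label matrix")
  h <- labelEntropy(p)
  vapply(split(h, obj$document_id), sum, numeric(1))
}
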