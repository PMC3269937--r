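## Composite system: per-candidate features from team outputs, confidence
## stratification, a deterministic L2-regularized linear classifier with
## modified Huber loss, and leave-one-out cross-validation whose scores
## form a composite run for TAP scoring.

#' Ensemble configuration
#'
#' @param nStrata Number of per-source confidence strata N (0 = binary
#'   presence features only); the benchmark experiments used N in
#'   \{0, 5, 10\}, giving 14, 84 and 154 features for 14 sources.
#' @param regularizationStrength L2 penalty on non-intercept weights
#'   (default 1e-4).
#' @param seed Recorded for provenance; training itself is deterministic.
#' @param maxEpochs Maximum optimizer iterations (default 200).
#' @return An [EnsembleConfig-class].
#' @export
ensembleConfig <- function(nStrata = 0L, regularizationStrength = 1e-4,
                           seed = 1L, maxEpochs = 200L) {
  methods::new("EnsembleConfig", nStrata = as.integer(nStrata),
               regularizationStrength = regularizationStrength,
               seed = as.integer(seed), maxEpochs = as.integer(maxEpochs))
}

#' Stratify a run's confidences into quantile bins
#'
#' Bins all of one source's confidence scores (pooled over documents, since
#' different sources' score scales are incomparable but one source's scale
#' is assumed consistent) into \code{nStrata} quantile groups from low (0)
#' to high (nStrata - 1). Bin boundaries sit at the i/N quantiles; values
#' tied with a boundary fall in the lower bin.
#'
#' @param run A [SourceRun-class] with at least one prediction.
#' @param nStrata Number of strata (>= 1).
#' @return data.frame with columns \code{document_id}, \code{identifier},
#'   \code{stratum} (0-based).
#' @export
stratifyConfidences <- function(run, nStrata) {
  stopifnot(nStrata >= 1)
  p <- predictions(run)
  if (!nrow(p)) stop("run has no predictions to stratify")
  stratum <- integer(nrow(p))
  if (nStrata > 1) {
    q <- stats::quantile(p$confidence, probs = seq_len(nStrata - 1) / nStrata,
                         names = FALSE, type = 7)
    stratum <- rowSums(outer(p$confidence, q, ">"))
  }
  data.frame(document_id = p$document_id, identifier = p$identifier,
             stratum = as.integer(stratum), stringsAsFactors = FALSE)
}

#' Build the candidate feature matrix
#'
#' One row per candidate (document, identifier) object; per source one
#' binary presence feature plus, when \code{nStrata > 0}, a one-hot block
#' over that source's confidence strata (all zero when the source did not
#' return the object). Feature dimension is M * (1 + N).
#'
#' @param runs List of [SourceRun-class] objects, the label matrix's
#'   sources in order (one best run per team in the benchmark setting).
#' @param candidates A [LabelMatrix-class] built from \code{runs} defining
#'   the candidate objects.
#' @param config An [EnsembleConfig-class].
#' @param gold Optional [GoldStandard-class]; when supplied, a binary label
#'   per object (1 if the identifier is annotated for the document).
#' @return List with \code{features} (numeric matrix), \code{labels}
#'   (integer vector or NULL), and \code{objects} (the candidates'
#'   data.frame).
#' @export
buildFeatureMatrix <- function(runs, candidates, config, gold = NULL) {
  ids <- vapply(runs, runId, character(1))
  if (!identical(ids, sources(candidates)))
    stop("runs must match the label matrix sources, in order")
  obj <- labelObjects(candidates)
  okey <- objectKey(obj$document_id, obj$identifier)
  n <- nrow(obj); m <- length(runs); ns <- config@nStrata
  x <- matrix(0, n, m * (1L + ns))
  colnames(x) <- unlist(lapply(ids, function(id) {
    c(paste0(id, ".present"),
      if (ns > 0) paste0(id, ".stratum", seq_len(ns) - 1L))
  }))
  x[, seq_len(m) * (1L + ns) - ns] <- deltaMatrix(candidates)
  if (ns > 0) {
    for (i in seq_len(m)) {
      st <- stratifyConfidences(runs[[i]], ns)
      st <- st[st$document_id %in% obj$document_id, , drop = FALSE]
      j <- match(objectKey(st$document_id, st$identifier), okey)
      keep <- !is.na(j)
      col0 <- (i - 1L) * (1L + ns) + 1L
      x[cbind(j[keep], col0 + 1L + st$stratum[keep])] <- 1
    }
  }
  labels <- NULL
  if (!is.null(gold)) {
    ann <- annotations(gold)
    labels <- as.integer(mapply(function(d, g) g %in% (ann[[d]] %||% character()),
                                obj$document_id, obj$identifier,
                                USE.NAMES = FALSE))
  }
  list(features = x, labels = labels, objects = obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## modified Huber loss of margins z = y * f:
##   z >=  1: 0
##   |z| < 1: (1 - z)^2
##   z <= -1: -4 z
modifiedHuberLoss <- function(z) {
  ifelse(z >= 1, 0, ifelse(z >= -1, (1 - z)^2, -4 * z))
}

modifiedHuberGrad <- function(z) {
  ifelse(z >= 1, 0, ifelse(z >= -1, -2 * (1 - z), -4))
}

#' Train the composite modified-Huber classifier
#'
#' Fits a linear score f(x) = w0 + w'x minimizing mean modified Huber loss
#' plus an L2 penalty on the non-intercept weights, by BFGS (the loss is
#' continuously differentiable). The optimization starts from zero weights
#' and is fully deterministic: identical data and configuration give
#' identical weights.
#'
#' @param features Numeric matrix, one row per training candidate.
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @param config An [EnsembleConfig-class].
#' @return Object of class \code{"compositeClassifier"} with elements
#'   \code{weights} (named, intercept first), \code{config}, and
#'   \code{value} (final objective). Use [predict()] to score candidates.
#' @export
trainCompositeClassifier <- function(features, labels, config = ensembleConfig()) {
  y <- ifelse(as.numeric(labels) > 0, 1, -1)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class")
  X <- cbind(1, features)
  lam <- config@regularizationStrength
  n <- nrow(X)
  obj <- function(w) {
    z <- y * drop(X %*% w)
    mean(modifiedHuberLoss(z)) + lam / 2 * sum(w[-1]^2)
  }
  grad <- function(w) {
    z <- y * drop(X %*% w)
    g <- drop(crossprod(X, modifiedHuberGrad(z) * y)) / n
    g[-1] <- g[-1] + lam * w[-1]
    g
  }
  fit <- stats::optim(numeric(ncol(X)), obj, grad, method = "BFGS",
                      control = list(maxit = config@maxEpochs,
                                     reltol = 1e-12))
  w <- fit$par
  names(w) <- c("(Intercept)", colnames(features))
  structure(list(weights = w, config = config, value = fit$value),
            class = "compositeClassifier")
}

#' @describeIn trainCompositeClassifier Score candidates with a trained
#'   classifier (higher = more likely positive).
#' @param object A \code{"compositeClassifier"}.
#' @param newdata Feature matrix with the training columns.
#' @param ... Ignored.
#' @export
predict.compositeClassifier <- function(object, newdata, ...) {
  drop(cbind(1, newdata) %*% object$weights)
}

#' Leave-one-out cross-validated composite run
#'
#' For every annotated document, trains the composite classifier on all
#' other documents' candidates (labelled by the gold standard) and scores
#' the held-out document's candidates; the pooled scores form a composite
#' [SourceRun-class] whose confidences are the classifier scores, which is
#' then TAP-scored against the gold standard. A fold whose training data
#' contain a single class falls back to scoring by source vote count (and
#' says so via a message).
#'
#' @param runs List of [SourceRun-class] objects (one best run per team).
#' @param gold A [GoldStandard-class] over at least 2 documents.
#' @param config An [EnsembleConfig-class].
#' @param kValues TAP-k values to evaluate (default c(5, 10, 20)).
#' @param zeroGoldPolicy Passed to [tapKScore()].
#' @param keepModels Keep each fold's weight vector in the result (for
#'   leakage auditing).
#' @return List with \code{run} (the composite [SourceRun-class]),
#'   \code{tap} (named numeric, one TAP per k), and optionally
#'   \code{models}.
#' @export
loocvComposite <- function(runs, gold, config = ensembleConfig(),
                           kValues = c(5, 10, 20),
                           zeroGoldPolicy = c("score", "exclude"),
                           keepModels = FALSE) {
  zeroGoldPolicy <- match.arg(zeroGoldPolicy)
  docs <- names(annotations(gold))
  if (length(docs) < 2L) stop("need at least 2 annotated documents")
  lm <- buildLabelMatrix(runs, documents = docs)
  fs <- buildFeatureMatrix(runs, lm, config, gold)
  obj <- fs$objects
  votes <- rowSums(deltaMatrix(lm))
  scores <- numeric(nrow(obj))
  models <- list()
  for (d in unique(obj$document_id)) {
    te <- obj$document_id == d
    tr <- !te
    yTr <- fs$labels[tr]
    if (length(unique(yTr)) < 2L) {
      message("fold '", d, "': single-class training data; falling back to vote-count scoring")
      scores[te] <- votes[te]
      if (keepModels) models[[d]] <- NULL
    } else {
      fit <- trainCompositeClassifier(fs$features[tr, , drop = FALSE], yTr,
                                      config)
      scores[te] <- predict(fit, fs$features[te, , drop = FALSE])
      if (keepModels) models[[d]] <- fit$weights
    }
  }
  comp <- newSourceRun(paste0("composite_N", config@nStrata),
                       data.frame(document_id = obj$document_id,
                                  identifier = obj$identifier,
                                  confidence = scores,
                                  stringsAsFactors = FALSE))
  tap <- vapply(kValues, function(k)
    tapScore(tapKScore(comp, gold, k, zeroGoldPolicy)), numeric(1))
  names(tap) <- paste0("TAP-", kValues)
  out <- list(run = comp, tap = tap)
  if (keepModels) out$models <- models
  out
}
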