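## Central S4 containers. Validity methods enforce the structural invariants
## that every downstream computation relies on; constructors canonicalize.

PRED_COLS <- c("document_id", "identifier", "rank", "confidence")

#' SourceRun: one ranked, confidence-scored submission
#'
#' A submission run from one labelling source (team). For each document it
#' holds an ordered list of predicted identifiers with confidence scores.
#' Within a document, ranks are consecutive integers starting at 1, no
#' (document, identifier) pair appears twice, and confidences are
#' non-increasing in rank (the canonical ordering sorts by confidence,
#' breaking ties by submitted rank and then identifier).
#'
#' @slot runId Single string naming the run (e.g. team + run label).
#' @slot predictions A data.frame with columns \code{document_id},
#'   \code{identifier}, \code{rank}, \code{confidence}, sorted by document
#'   and rank.
#'
#' @seealso [readSubmission()], [newSourceRun()]
#' @export
setClass("SourceRun", representation(
  runId = "character",
  predictions = "data.frame"
))

setValidity("SourceRun", function(object) {
  msg <- character()
  if (length(object@runId) != 1L || is.na(object@runId) || !nzchar(object@runId))
    msg <- c(msg, "'runId' must be a single non-empty string")
  p <- object@predictions
  if (!all(PRED_COLS %in% names(p)))
    return(paste("predictions must have columns:", paste(PRED_COLS, collapse = ", ")))
  if (nrow(p)) {
    if (!is.numeric(p$confidence) || any(!is.finite(p$confidence)))
      msg <- c(msg, "confidences must be finite numbers")
    if (anyDuplicated(paste0(p$document_id, "\r", p$identifier)))
      msg <- c(msg, "duplicate (document, identifier) pair")
    bad <- vapply(split(seq_len(nrow(p)), p$document_id), function(i) {
      r <- p$rank[i]
      !identical(as.integer(sort(r)), seq_along(i)) ||
        is.unsorted(r) ||
        is.unsorted(rev(p$confidence[i][order(r)]))
    }, logical(1))
    if (any(bad))
      msg <- c(msg, paste0("within-document ranks must be 1..n with non-increasing confidence (", paste(names(bad)[bad], collapse = ", "), ")"))
  }
  if (length(msg)) msg else TRUE
})

#' GoldStandard: per-document sets of correct identifiers
#'
#' Reference annotations: a map from document id to the (possibly empty) set
#' of correct identifiers. The silver standard extracted by
#' [extractSilverStandard()] has the same shape.
#'
#' @slot annotations Named list; each element is a character vector of
#'   unique identifiers (possibly empty).
#'
#' @seealso [readGold()], [newGoldStandard()]
#' @export
setClass("GoldStandard", representation(annotations = "list"))

setValidity("GoldStandard", function(object) {
  a <- object@annotations
  if (length(a)) {
    if (is.null(names(a)) || any(!nzchar(names(a))) || anyDuplicated(names(a)))
      return("annotations must be uniquely named by document id")
    ok <- vapply(a, function(v) {
      is.character(v) && !anyNA(v) && all(nzchar(v)) && !anyDuplicated(v)
    }, logical(1))
    if (!all(ok)) return("each annotation set must be unique non-empty identifier strings")
  }
  TRUE
})

#' LabelMatrix: binary labels of (document, identifier) objects by sources
#'
#' The N x M indicator matrix underlying the EM consensus model: entry
#' (j, i) is 1 if source i returned object j (a (document, identifier)
#' pair) and 0 otherwise. Objects are the union of all pairs returned by
#' the sources, sorted lexicographically by document then identifier, so
#' every row has at least one 1.
#'
#' @slot objects data.frame with columns \code{document_id},
#'   \code{identifier}; one row per object, in canonical order.
#' @slot sources Character vector of run ids (columns), in input order.
#' @slot delta Integer 0/1 matrix, \code{nrow(objects)} x
#'   \code{length(sources)}.
#'
#' @seealso [buildLabelMatrix()]
#' @export
setClass("LabelMatrix", representation(
  objects = "data.frame",
  sources = "character",
  delta = "matrix"
))

setValidity("LabelMatrix", function(object) {
  msg <- character()
  if (!all(c("document_id", "identifier") %in% names(object@objects)))
    return("objects must have columns document_id, identifier")
  n <- nrow(object@objects); m <- length(object@sources)
  if (!identical(dim(object@delta), c(n, m)))
    msg <- c(msg, "delta dimensions must match objects x sources")
  if (anyDuplicated(object@sources))
    msg <- c(msg, "source ids must be unique")
  if (n && anyDuplicated(paste0(object@objects$document_id, "\r", object@objects$identifier)))
    msg <- c(msg, "objects must be unique (document, identifier) pairs")
  if (length(object@delta) && !all(object@delta %in% c(0L, 1L)))
    msg <- c(msg, "delta entries must be 0 or 1")
  else if (n && m && any(rowSums(object@delta) < 1))
    msg <- c(msg, "every object must be labelled 1 by at least one source")
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: EM consensus probabilities and source quality
#'
#' Output of [runEM()]: per-object posterior probabilities of correctness,
#' per-source sensitivity/specificity estimates, and the penalized
#' log-posterior trace across iterations.
#'
#' @slot p Numeric vector in [0,1], aligned with the LabelMatrix objects.
#' @slot profiles data.frame with columns \code{run_id},
#'   \code{sensitivity}, \code{specificity}; values strictly inside (0,1)
#'   thanks to Laplace smoothing.
#' @slot prior Uniform prior probability that an object is correct.
#' @slot iterations Number of EM iterations performed.
#' @slot converged Whether the max-abs probability change fell below the
#'   tolerance.
#' @slot objectiveTrace Penalized log-posterior (marginal log-likelihood
#'   plus Beta(2,2) log-prior on each sensitivity and specificity), one
#'   value per iteration; non-decreasing up to numerical tolerance.
#'
#' @export
setClass("ConsensusResult", representation(
  p = "numeric",
  profiles = "data.frame",
  prior = "numeric",
  iterations = "integer",
  converged = "logical",
  objectiveTrace = "numeric"
))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p must lie in [0,1]")
  pr <- object@profiles
  if (!all(c("run_id", "sensitivity", "specificity") %in% names(pr)))
    msg <- c(msg, "profiles must have columns run_id, sensitivity, specificity")
  else if (nrow(pr) && (any(pr$sensitivity <= 0 | pr$sensitivity >= 1) ||
                        any(pr$specificity <= 0 | pr$specificity >= 1)))
    msg <- c(msg, "profile values must lie strictly inside (0,1)")
  if (length(object@prior) != 1L || object@prior <= 0 || object@prior >= 1)
    msg <- c(msg, "prior must be a single value in (0,1)")
  if (length(msg)) msg else TRUE
})

#' TapResult: threshold average precision of one run
#'
#' Output of [tapKScore()]: the selected confidence threshold, per-query
#' average precision with cutoff and terminal penalty, and their mean.
#'
#' @slot k The tolerated median number of false positives.
#' @slot thresholdX Selected score threshold; \code{-Inf} is the
#'   retrieve-all sentinel (no score level yields a median of k false
#'   positives).
#' @slot perQuery data.frame with columns \code{document_id}, \code{P},
#'   \code{apc}, \code{terminalPrecision}, \code{apcp},
#'   \code{nFalsePositives}.
#' @slot tap Arithmetic mean of the per-query \code{apcp} values.
#'
#' @export
setClass("TapResult", representation(
  k = "integer",
  thresholdX = "numeric",
  perQuery = "data.frame",
  tap = "numeric"
))

setValidity("TapResult", function(object) {
  q <- object@perQuery
  need <- c("document_id", "P", "apc", "terminalPrecision", "apcp", "nFalsePositives")
  if (!all(need %in% names(q)))
    return(paste("perQuery must have columns:", paste(need, collapse = ", ")))
  if (nrow(q) && (any(q$apcp < -1e-12) || any(q$apcp > 1 + 1e-12)))
    return("apcp values must lie in [0,1]")
  TRUE
})

#' SelectionResult: entropy-based document selection
#'
#' Output of [selectDocuments()]: mean per-document entropy scores over
#' sampling trials and the selected top-scoring documents.
#'
#' @slot docScores Named numeric vector of mean entropy scores.
#' @slot nTrials Number of sampling trials averaged over.
#' @slot chosen Document ids with the highest mean scores, ties broken
#'   lexicographically.
#' @slot seed Seed used for run sampling.
#'
#' @export
setClass("SelectionResult", representation(
  docScores = "numeric",
  nTrials = "integer",
  chosen = "character",
  seed = "integer"
))

#' SimConfig: synthetic benchmark generator settings
#'
#' Study conditions for the synthetic corpus: per-document gold gene counts
#' follow a negative binomial (default mu = 18, size = 1, giving median 12,
#' matching the full-test-set statistics of the benchmark this package
#' models); each document carries a pool of decoy identifiers; each source
#' labels pool members independently with its sensitivity/specificity; and
#' returned ids receive Beta-distributed confidences conditional on truth.
#'
#' @slot nDocs Number of documents.
#' @slot geneCountMean,geneCountSize Negative binomial mean and size for
#'   per-document gold gene counts.
#' @slot candidatePoolPerDoc Number of decoy identifiers per document.
#' @slot sensitivity,specificity True per-source profiles, in [0,1].
#' @slot confTrueShape,confFalseShape Beta shape pairs for confidences of
#'   truly-correct and incorrect returned ids.
#' @slot seed Base seed; all outputs are reproducible from (config, seed).
#'
#' @seealso [simConfig()], [simulateBenchmark()]
#' @export
setClass("SimConfig", representation(
  nDocs = "integer",
  geneCountMean = "numeric",
  geneCountSize = "numeric",
  candidatePoolPerDoc = "integer",
  sensitivity = "numeric",
  specificity = "numeric",
  confTrueShape = "numeric",
  confFalseShape = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nDocs < 1L) msg <- c(msg, "nDocs must be >= 1")
  if (length(object@sensitivity) != length(object@specificity) ||
      !length(object@sensitivity))
    msg <- c(msg, "sensitivity and specificity must be non-empty and equal length")
  if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
      any(object@specificity < 0 | object@specificity > 1))
    msg <- c(msg, "profiles must lie in [0,1]")
  if (object@geneCountMean < 0 || object@geneCountSize <= 0)
    msg <- c(msg, "gene count model parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' EnsembleConfig: composite classifier settings
#'
#' @slot nStrata Number of per-source confidence strata N (0 = binary
#'   presence features only). Feature dimension is M * (1 + N) for M
#'   sources.
#' @slot regularizationStrength L2 penalty on non-intercept weights.
#' @slot seed Recorded for provenance; training is deterministic.
#' @slot maxEpochs Maximum optimizer iterations.
#'
#' @seealso [ensembleConfig()], [trainCompositeClassifier()]
#' @export
setClass("EnsembleConfig", representation(
  nStrata = "integer",
  regularizationStrength = "numeric",
  seed = "integer",
  maxEpochs = "integer"
))

setValidity("EnsembleConfig", function(object) {
  msg <- character()
  if (!object@nStrata %in% c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L) &&
      object@nStrata < 0L)
    msg <- c(msg, "nStrata must be a non-negative integer")
  if (object@regularizationStrength <= 0)
    msg <- c(msg, "regularizationStrength must be positive")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- constructors ----------------------------------------------------

objectKey <- function(document_id, identifier) paste0(document_id, "\r", identifier)

#' Construct a SourceRun
#'
#' Builds a [SourceRun-class] from a prediction table. With
#' \code{canonicalize = TRUE} (the default) predictions are re-ordered per
#' document by decreasing confidence, ties broken by submitted rank then
#' identifier, and ranks renumbered 1..n; this is the canonical ordering
#' that makes all downstream results bit-reproducible. With
#' \code{canonicalize = FALSE} the table must already satisfy the class
#' invariants.
#'
#' @param runId Single string naming the run.
#' @param predictions data.frame with columns \code{document_id},
#'   \code{identifier}, \code{confidence}, and (if not canonicalizing, or
#'   for tie-breaking) \code{rank}.
#' @param canonicalize Re-sort and renumber ranks (see Details).
#' @return A validated [SourceRun-class].
#' @export
newSourceRun <- function(runId, predictions, canonicalize = TRUE) {
  p <- as.data.frame(predictions)
  if (is.null(p$rank)) p$rank <- stats::ave(p$confidence, p$document_id,
                                            FUN = seq_along)
  p$document_id <- as.character(p$document_id)
  p$identifier <- as.character(p$identifier)
  p$rank <- as.integer(p$rank)
  p$confidence <- as.numeric(p$confidence)
  if (canonicalize && nrow(p)) {
    o <- order(p$document_id, -p$confidence, p$rank, p$identifier, method = "radix")
    p <- p[o, , drop = FALSE]
    p$rank <- stats::ave(seq_len(nrow(p)), p$document_id, FUN = seq_along)
  }
  rownames(p) <- NULL
  methods::new("SourceRun", runId = as.character(runId),
               predictions = p[, PRED_COLS, drop = FALSE])
}

#' Construct a GoldStandard
#'
#' @param annotations Named list of character vectors of identifiers
#'   (duplicates are collapsed); empty vectors declare documents with no
#'   correct identifiers.
#' @return A validated [GoldStandard-class].
#' @export
newGoldStandard <- function(annotations = list()) {
  a <- lapply(annotations, function(v) sort(unique(as.character(v))))
  if (length(a)) a <- a[order(names(a), method = "radix")]
  methods::new("GoldStandard", annotations = a)
}

#' @rdname accessors
#' @export
setMethod("runId", "SourceRun", function(x) x@runId)

#' @rdname accessors
#' @export
setMethod("predictions", "SourceRun", function(x) x@predictions)

#' @rdname accessors
#' @export
setMethod("annotations", "GoldStandard", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("deltaMatrix", "LabelMatrix", function(x) x@delta)

#' @rdname accessors
#' @export
setMethod("labelObjects", "LabelMatrix", function(x) x@objects)

#' @rdname accessors
#' @export
setMethod("sources", "LabelMatrix", function(x) x@sources)

#' @rdname accessors
#' @export
setMethod("probabilities", "ConsensusResult", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("sourceProfiles", "ConsensusResult", function(x) x@profiles)

#' @rdname accessors
#' @export
setMethod("tapScore", "TapResult", function(x) x@tap)

#' @rdname accessors
#' @export
setMethod("perQueryEvals", "TapResult", function(x) x@perQuery)

#' @rdname accessors
#' @export
setMethod("thresholdX", "TapResult", function(x) x@thresholdX)

#' @rdname accessors
#' @export
setMethod("chosenDocuments", "SelectionResult", function(x) x@chosen)

#' @rdname accessors
#' @export
setMethod("documentScores", "SelectionResult", function(x) x@docScores)

## ---- show methods ----------------------------------------------------

setMethod("show", "SourceRun", function(object) {
  p <- object@predictions
  cat("SourceRun '", object@runId, "': ", nrow(p), " predictions over ",
      length(unique(p$document_id)), " documents\n", sep = "")
})

setMethod("show", "GoldStandard", function(object) {
  a <- object@annotations
  cat("GoldStandard: ", length(a), " documents, ",
      sum(lengths(a)), " positive annotations\n", sep = "")
})

setMethod("show", "LabelMatrix", function(object) {
  cat("LabelMatrix: ", nrow(object@objects), " objects x ",
      length(object@sources), " sources (density ",
      format(mean(object@delta), digits = 3), ")\n", sep = "")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: ", length(object@p), " objects, ",
      nrow(object@profiles), " sources; prior ", object@prior,
      "; ", object@iterations, " iterations (",
      if (object@converged) "converged" else "NOT converged", ")\n", sep = "")
})

setMethod("show", "TapResult", function(object) {
  cat("TapResult: TAP-", object@k, " = ", format(object@tap, digits = 4),
      " at threshold ",
      if (is.infinite(object@thresholdX)) "retrieve-all"
      else format(object@thresholdX, digits = 4),
      " over ", nrow(object@perQuery), " queries\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: ", length(object@chosen), " documents chosen from ",
      length(object@docScores), " (", object@nTrials, " trials, seed ",
      object@seed, ")\n", sep = "")
})
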