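#' Entropy-based selection of discriminative evaluation documents
#'
#' Repeats the following trial \code{nTrials} times: sample uniformly one
#' run per team (teams processed in lexicographic order so the random
#' stream is reproducible), build the label matrix over all documents,
#' run the EM consensus model, and score every document by its entropy sum
#' ([scoreDocuments()]). Documents absent from a trial's sampled runs score
#' 0 in that trial. The \code{nDocs} documents with the highest mean score
#' over trials are selected; ties are broken lexicographically by document
#' id.
#'
#' @param teamRuns Named list: team id -> list of that team's
#'   [SourceRun-class] runs (each team needs at least one run).
#' @param nDocs Number of documents to select (default 50).
#' @param nTrials Number of sampling trials (default 100).
#' @param prior Prior passed to [runEM()] (default 0.5).
#' @param seed Integer seed for the run sampling.
#' @param tol,maxIter Passed to [runEM()].
#' @return A [SelectionResult-class].
#' @export
selectDocuments <- function(teamRuns, nDocs = 50L, nTrials = 100L,
                            prior = 0.5, seed = 1L, tol = 1e-8,
                            maxIter = 1000L) {
  if (!length(teamRuns) || is.null(names(teamRuns)) ||
      any(!nzchar(names(teamRuns))))
    stop("'teamRuns' must be a non-empty named list of run lists")
  if (any(lengths(teamRuns) < 1L)) stop("every team needs at least one run")
  teams <- sort(names(teamRuns), method = "radix")
  allDocs <- sort(unique(unlist(lapply(unlist(teamRuns, recursive = FALSE),
                                       function(r) predictions(r)$document_id),
                                use.names = FALSE)), method = "radix")
  if (nDocs > length(allDocs))
    stop("nDocs (", nDocs, ") exceeds the ", length(allDocs),
         " available documents")
  scoreSum <- stats::setNames(numeric(length(allDocs)), allDocs)
  withSeed(seed, {
    for (trial in seq_len(nTrials)) {
      picked <- lapply(teams, function(tm) {
        rs <- teamRuns[[tm]]
        rs[[sample.int(length(rs), 1L)]]
      })
      lm <- buildLabelMatrix(picked)
      fit <- suppressWarnings(runEM(lm, prior = prior, tol = tol,
                                    maxIter = maxIter))
      sc <- scoreDocuments(fit, lm)
      scoreSum[names(sc)] <- scoreSum[names(sc)] + sc
    }
  })
  meanScores <- scoreSum / nTrials
  ord <- order(-meanScores, names(meanScores), method = "radix")
  methods::new("SelectionResult", docScores = meanScores,
               nTrials = as.integer(nTrials),
               chosen = names(meanScores)[ord][seq_len(nDocs)],
               seed = as.integer(seed))
}

#' Evaluate an expression with a private, restored RNG state
#'
#' Seeds the random number generator, evaluates \code{expr}, and restores
#' the caller's RNG state afterwards, so seeded helpers never perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @examples
#' withSeed(1, runif(2))
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
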