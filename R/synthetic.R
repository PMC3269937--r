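## Seeded synthetic benchmark generator. The observation model mirrors the
## EM likelihood exactly: each source labels each candidate independently,
## returning a truly-correct id with its sensitivity and an incorrect one
## with one minus its specificity, so EM estimates are consistent as the
## number of objects grows.

#' Create a synthetic benchmark configuration
#'
#' Defaults emulate the statistical structure of the full 507-article test
#' set of the gene normalization benchmark this package models:
#' per-document gold gene counts are negative binomial with mean 18 and
#' size 1 (median 12), and 14 sources span a realistic quality range.
#' Confidences of returned ids are Beta(5,2) when truly correct and
#' Beta(2,5) otherwise, giving informative but imperfect rankings.
#'
#' @param nDocs Number of documents (default 100).
#' @param geneCountMean,geneCountSize Negative binomial parameters for
#'   per-document gold counts (defaults 18 and 1).
#' @param candidatePoolPerDoc Decoy identifiers per document (default 50).
#' @param sensitivity,specificity True source profiles; defaults are 14
#'   sources with sensitivity 0.60..0.95 and specificity 0.95..0.60.
#' @param confTrueShape,confFalseShape Beta shapes for confidences of
#'   correct and incorrect returned ids.
#' @param seed Base seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nDocs = 100L,
                      geneCountMean = 18,
                      geneCountSize = 1,
                      candidatePoolPerDoc = 50L,
                      sensitivity = seq(0.60, 0.95, length.out = 14),
                      specificity = seq(0.95, 0.60, length.out = 14),
                      confTrueShape = c(5, 2),
                      confFalseShape = c(2, 5),
                      seed = 1L) {
  methods::new("SimConfig", nDocs = as.integer(nDocs),
               geneCountMean = geneCountMean, geneCountSize = geneCountSize,
               candidatePoolPerDoc = as.integer(candidatePoolPerDoc),
               sensitivity = sensitivity, specificity = specificity,
               confTrueShape = confTrueShape, confFalseShape = confFalseShape,
               seed = as.integer(seed))
}

#' Configuration for the rare-truth regime
#'
#' A preset in which only about 1\% of the ids returned by sources are
#' correct, the marginal regime observed on the benchmark's full test set:
#' two sources with sensitivity 0.85 and specificity 0.90 labelling
#' documents with 15000 decoys each, so the expected correct fraction of
#' returned ids is 18*0.85 / (18*0.85 + 15000*0.10) ~ 1\%.
#'
#' @param nDocs Number of documents (default 60, giving > 1e5 returned
#'   ids).
#' @param seed Base seed.
#' @return A [SimConfig-class].
#' @export
rareTruthConfig <- function(nDocs = 60L, seed = 1L) {
  simConfig(nDocs = nDocs, candidatePoolPerDoc = 15000L,
            sensitivity = rep(0.85, 2), specificity = rep(0.90, 2),
            seed = seed)
}

#' Simulate a gold corpus with candidate pools
#'
#' Draws each document's gold gene count from the configured negative
#' binomial (0 is allowed), mints unique gold identifiers, and pads each
#' document's candidate pool with decoy identifiers that never appear in
#' any gold set. Fully reproducible from (config, seed).
#'
#' @param config A [SimConfig-class].
#' @param seed Seed (defaults to the config's).
#' @return List with \code{gold} (a [GoldStandard-class]) and \code{pools}
#'   (named list of candidate identifier vectors per document).
#' @export
simulateGoldCorpus <- function(config, seed = config@seed) {
  docs <- sprintf("D%05d", seq_len(config@nDocs))
  withSeed(seed, {
    counts <- stats::rnbinom(config@nDocs, size = config@geneCountSize,
                             mu = config@geneCountMean)
    total <- sum(counts) + config@nDocs * config@candidatePoolPerDoc
    ids <- sprintf("G%07d", seq_len(total))
    ann <- vector("list", config@nDocs)
    pools <- vector("list", config@nDocs)
    at <- 0L
    for (i in seq_len(config@nDocs)) {
      g <- ids[at + seq_len(counts[i])]
      at <- at + counts[i]
      d <- ids[at + seq_len(config@candidatePoolPerDoc)]
      at <- at + config@candidatePoolPerDoc
      ann[[i]] <- g
      pools[[i]] <- c(g, d)
    }
    names(ann) <- docs
    names(pools) <- docs
    list(gold = newGoldStandard(ann), pools = pools)
  })
}

#' Simulate source runs over a gold corpus
#'
#' Each source labels every candidate-pool member independently: truly
#' correct ids are returned with that source's sensitivity, incorrect ones
#' with one minus its specificity. Returned ids draw confidences from the
#' truth-conditional Beta distributions and are ranked by decreasing
#' confidence.
#'
#' @param gold A [GoldStandard-class] (from [simulateGoldCorpus()]).
#' @param pools Candidate pools aligned with \code{gold}.
#' @param config A [SimConfig-class].
#' @param seed Seed (defaults to config seed + 1 so corpus and runs use
#'   distinct streams).
#' @return List of [SourceRun-class] objects, named S01, S02, ...
#' @export
simulateSourceRuns <- function(gold, pools, config, seed = config@seed + 1L) {
  ann <- annotations(gold)
  docs <- names(pools)
  docVec <- rep(docs, lengths(pools))
  idVec <- unlist(pools, use.names = FALSE)
  isTrue <- unlist(lapply(docs, function(d) pools[[d]] %in% ann[[d]]),
                   use.names = FALSE)
  m <- length(config@sensitivity)
  runIds <- sprintf("S%02d", seq_len(m))
  withSeed(seed, {
    lapply(seq_len(m), function(i) {
      pReturn <- ifelse(isTrue, config@sensitivity[i], 1 - config@specificity[i])
      ret <- stats::runif(length(pReturn)) < pReturn
      nTrue <- sum(isTrue & ret)
      nFalse <- sum(ret) - nTrue
      conf <- numeric(sum(ret))
      retTrue <- isTrue[ret]
      conf[retTrue] <- stats::rbeta(nTrue, config@confTrueShape[1],
                                    config@confTrueShape[2])
      conf[!retTrue] <- stats::rbeta(nFalse, config@confFalseShape[1],
                                     config@confFalseShape[2])
      newSourceRun(runIds[i],
                   data.frame(document_id = docVec[ret],
                              identifier = idVec[ret],
                              confidence = conf,
                              stringsAsFactors = FALSE))
    })
  })
}

#' Simulate a full benchmark
#'
#' Convenience wrapper: [simulateGoldCorpus()] then [simulateSourceRuns()].
#'
#' @param config A [SimConfig-class].
#' @return List with \code{gold}, \code{pools}, \code{runs}, and
#'   \code{truthProfiles} (data.frame of the generative sensitivity and
#'   specificity per source).
#' @export
simulateBenchmark <- function(config) {
  corpus <- simulateGoldCorpus(config)
  runs <- simulateSourceRuns(corpus$gold, corpus$pools, config)
  list(gold = corpus$gold, pools = corpus$pools, runs = runs,
       truthProfiles = data.frame(
         run_id = vapply(runs, runId, character(1)),
         sensitivity = config@sensitivity,
         specificity = config@specificity,
         stringsAsFactors = FALSE))
}

#' Fraction of returned ids that are correct
#'
#' @param runs List of [SourceRun-class] objects.
#' @param gold A [GoldStandard-class].
#' @return List with \code{fraction} and \code{nReturned} (pooled over all
#'   runs).
#' @export
correctReturnedFraction <- function(runs, gold) {
  ann <- annotations(gold)
  tot <- 0L; correct <- 0L
  for (r in runs) {
    p <- predictions(r)
    tp <- mapply(function(d, g) g %in% ann[[d]], p$document_id, p$identifier,
                 USE.NAMES = FALSE)
    tot <- tot + nrow(p)
    correct <- correct + sum(tp)
  }
  list(fraction = correct / tot, nReturned = tot)
}

#' EM parameter-recovery experiment
#'
#' Simulates a benchmark, runs the EM consensus model on the label matrix
#' of all returned ids, and reports per-source absolute profile errors
#' against the generative truth, the silver standard's precision/recall/F1
#' against the simulated gold standard, the same for each individual source
#' and for a majority vote baseline (an object is accepted when at least
#' half the sources return it).
#'
#' @param config A [SimConfig-class].
#' @param prior Prior for [runEM()]; \code{NULL} (default) uses the
#'   realized truth prevalence among the matrix objects.
#' @param tol,maxIter Passed to [runEM()].
#' @return List with \code{profileErrors} (data.frame), \code{maxProfileError},
#'   \code{silver} (PRF), \code{majority} (PRF), \code{sourcePRF}
#'   (data.frame per source), \code{prior}, \code{nObjects} and \code{fit}.
#' @export
recoveryExperiment <- function(config, prior = NULL, tol = 1e-8,
                               maxIter = 1000L) {
  sim <- simulateBenchmark(config)
  lm <- buildLabelMatrix(sim$runs)
  obj <- labelObjects(lm)
  ann <- annotations(sim$gold)
  truth <- mapply(function(d, g) g %in% ann[[d]], obj$document_id,
                  obj$identifier, USE.NAMES = FALSE)
  if (is.null(prior)) prior <- mean(truth)
  fit <- suppressWarnings(runEM(lm, prior = prior, tol = tol,
                                maxIter = maxIter))
  prof <- sourceProfiles(fit)
  errs <- data.frame(run_id = prof$run_id,
                     sensitivityError = abs(prof$sensitivity - config@sensitivity),
                     specificityError = abs(prof$specificity - config@specificity),
                     stringsAsFactors = FALSE)
  prf <- function(predPositive) {
    precisionRecallF1(sum(lengths(ann)), sum(predPositive),
                      sum(predPositive & truth))
  }
  d <- deltaMatrix(lm)
  silver <- prf(probabilities(fit) >= 0.5)
  majority <- prf(rowSums(d) >= ncol(d) / 2)
  sourcePRF <- do.call(rbind, lapply(seq_len(ncol(d)), function(i) {
    v <- prf(d[, i] == 1L)
    data.frame(run_id = sources(lm)[i], precision = v["precision"],
               recall = v["recall"], f1 = v["f1"], row.names = NULL)
  }))
  list(profileErrors = errs,
       maxProfileError = max(errs$sensitivityError, errs$specificityError),
       silver = silver, majority = majority, sourcePRF = sourcePRF,
       prior = prior, nObjects = nrow(obj), fit = fit)
}
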