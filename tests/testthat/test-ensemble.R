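test_that("confidence stratification uses pooled per-source quantiles", {
  run <- makeRun("A", rep("D1", 10), paste0("G", 1:10), 10:1)
  st <- stratifyConfidences(run, 5)
  byConf <- st$stratum[match(paste0("G", 1:10), st$identifier)]
  expect_equal(byConf, c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L))
  ## degenerate: equal confidences all land in bin 0; N = 1 likewise
  eq <- makeRun("A", rep("D1", 4), paste0("G", 1:4), rep(2, 4))
  expect_true(all(stratifyConfidences(eq, 5)$stratum == 0L))
  expect_true(all(stratifyConfidences(run, 1)$stratum == 0L))
  expect_error(stratifyConfidences(run, 0))
})

test_that("feature dimension is M * (1 + N) with consistent one-hot blocks", {
  sim <- simulateBenchmark(simConfig(nDocs = 6, candidatePoolPerDoc = 10,
                                     seed = 2))
  lm <- buildLabelMatrix(sim$runs)
  for (ns in c(0L, 5L, 10L)) {
    fs <- buildFeatureMatrix(sim$runs, lm, ensembleConfig(nStrata = ns),
                             sim$gold)
    expect_equal(ncol(fs$features), 14 * (1 + ns))
    expect_equal(nrow(fs$features), nrow(labelObjects(lm)))
    if (ns > 0) {
      for (i in seq_len(14)) {
        block <- fs$features[, ((i - 1) * (1 + ns) + 1):(i * (1 + ns))]
        strata <- block[, -1, drop = FALSE]
        ## at most one stratum bit, and only where the presence bit is set
        expect_true(all(rowSums(strata) <= 1))
        expect_true(all(rowSums(strata) <= block[, 1]))
        expect_true(all(block[, 1] == 0 | rowSums(strata) == 1))
      }
    }
  }
  ## labels come from the gold standard
  fs0 <- buildFeatureMatrix(sim$runs, lm, ensembleConfig(), sim$gold)
  obj <- fs0$objects
  ann <- annotations(sim$gold)
  expect_equal(fs0$labels,
               as.integer(mapply(function(d, g) g %in% ann[[d]],
                                 obj$document_id, obj$identifier)),
               ignore_attr = TRUE)
})

test_that("the modified-Huber classifier separates separable data deterministically", {
  set.seed(1)
  x <- cbind(f1 = c(rnorm(30, 2), rnorm(30, -2)), f2 = rnorm(60))
  y <- rep(c(1, 0), each = 30)
  fit <- trainCompositeClassifier(x, y)
  expect_equal(as.integer(predict(fit, x) > 0), y, ignore_attr = TRUE)
  fit2 <- trainCompositeClassifier(x, y)
  expect_identical(fit$weights, fit2$weights)
  expect_error(trainCompositeClassifier(x, rep(1, 60)), "single class")
})

test_that("a feature identical to the label dominates and ranks held-out data perfectly", {
  set.seed(2)
  y <- rbinom(80, 1, 0.4)
  x <- cbind(oracle = y, noise1 = rnorm(80), noise2 = rnorm(80))
  fit <- trainCompositeClassifier(x[1:60, ], y[1:60])
  w <- fit$weights
  expect_gt(abs(w[["oracle"]]), max(abs(w[c("noise1", "noise2")])))
  sc <- predict(fit, x[61:80, ])
  expect_true(min(sc[y[61:80] == 1]) > max(sc[y[61:80] == 0]))
})

test_that("identical teams give a composite equal to the common team", {
  sim <- simulateBenchmark(simConfig(nDocs = 10, candidatePoolPerDoc = 10,
                                     sensitivity = rep(0.85, 3),
                                     specificity = rep(0.9, 3), seed = 4))
  one <- sim$runs[[1]]
  clones <- lapply(1:3, function(i) newSourceRun(paste0("c", i),
                                                 predictions(one)))
  res <- loocvComposite(clones, sim$gold, ensembleConfig(nStrata = 5))
  for (k in c(5, 10, 20)) {
    teamTap <- tapScore(tapKScore(one, sim$gold, k))
    expect_equal(unname(res$tap[[paste0("TAP-", k)]]), teamTap,
                 tolerance = 0.011)
  }
})

test_that("folds never see their own document (no leakage)", {
  sim <- simulateBenchmark(simConfig(nDocs = 6, candidatePoolPerDoc = 8,
                                     sensitivity = rep(0.8, 4),
                                     specificity = rep(0.85, 4), seed = 8))
  cfg <- ensembleConfig(nStrata = 0)
  full <- loocvComposite(sim$runs, sim$gold, cfg, keepModels = TRUE)
  d <- names(annotations(sim$gold))[1]
  ## retrain fold d by hand on a matrix from which d's rows are deleted
  lm <- buildLabelMatrix(sim$runs, documents = names(annotations(sim$gold)))
  fs <- buildFeatureMatrix(sim$runs, lm, cfg, sim$gold)
  tr <- fs$objects$document_id != d
  manual <- trainCompositeClassifier(fs$features[tr, ], fs$labels[tr], cfg)
  expect_equal(full$models[[d]], manual$weights, tolerance = 1e-12)
})

test_that("two-document LOOCV fold membership is exactly complementary", {
  a <- makeRun("A", c("D1", "D2"), c("G1", "G2"), c(0.9, 0.9))
  b <- makeRun("B", c("D1", "D1", "D2"), c("G1", "G9", "G3"),
               c(0.9, 0.4, 0.9))
  gold <- newGoldStandard(list(D1 = "G1", D2 = "G2"))
  res <- suppressMessages(loocvComposite(list(a, b), gold,
                                         ensembleConfig(), kValues = 5))
  p <- predictions(res$run)
  expect_setequal(unique(p$document_id), c("D1", "D2"))
  ## candidate set per document is the union of the runs' predictions
  expect_setequal(p$identifier[p$document_id == "D1"], c("G1", "G9"))
  expect_setequal(p$identifier[p$document_id == "D2"], c("G2", "G3"))
})

test_that("single-class folds fall back to vote-count scoring with a message", {
  ## gold covers none of D2's candidates and training on D1 only is fine;
  ## make D1's training (i.e. D2's rows) single-class
  a <- makeRun("A", c("D1", "D2"), c("G1", "G2"), c(0.9, 0.9))
  b <- makeRun("B", c("D1", "D2"), c("G1", "G2"), c(0.8, 0.8))
  gold <- newGoldStandard(list(D1 = "G1", D2 = character()))
  expect_message(res <- loocvComposite(list(a, b), gold, ensembleConfig(),
                                       kValues = 5),
                 "single-class")
  expect_s4_class(res$run, "SourceRun")
})

test_that("a composite of one gold-equal and several noisy sources keeps the signal", {
  ## concentrated gold counts (negbin size 20 around mean 18): a classifier
  ## must score every candidate, so its TAP pays a terminal-precision cost
  ## at the cutoff that the abstaining gold-equal run never pays; with
  ## sizeable gold sets a perfect ranking keeps that cost small
  sim <- simulateBenchmark(simConfig(nDocs = 12, candidatePoolPerDoc = 15,
                                     geneCountSize = 20,
                                     sensitivity = rep(0.5, 3),
                                     specificity = rep(0.75, 3),
                                     seed = 10))
  ann <- annotations(sim$gold)
  ann <- ann[lengths(ann) > 0]
  oracleRun <- makeRun("oracle",
                       rep(names(ann), lengths(ann)),
                       unlist(ann, use.names = FALSE),
                       rep(0.9, sum(lengths(ann))))
  runs <- c(list(oracleRun), sim$runs)
  res <- suppressMessages(loocvComposite(runs, sim$gold,
                                         ensembleConfig(nStrata = 5),
                                         kValues = 5,
                                         zeroGoldPolicy = "exclude"))
  taps <- vapply(runs, function(r)
    tapScore(tapKScore(r, sim$gold, 5, zeroGoldPolicy = "exclude")),
    numeric(1))
  ## beats the average source and retains >= 95% of the gold-equal team
  expect_gte(res$tap[["TAP-5"]], mean(taps))
  expect_gte(res$tap[["TAP-5"]], 0.95 * max(taps) - 1e-9)
})
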