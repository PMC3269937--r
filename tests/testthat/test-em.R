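test_that("probabilities initialize to the positive label fraction", {
  delta <- cbind(c(1, 1, 0), c(1, 0, 0), c(1, 0, 1))
  lm <- randomLabelMatrix(10, 14, seed = 1)
  expect_equal(initializeProbabilities(lm),
               rowSums(deltaMatrix(lm)) / 14)
  lm3 <- randomLabelMatrix(6, 3, seed = 2)
  p <- initializeProbabilities(lm3)
  expect_true(all(p %in% c(1 / 3, 2 / 3, 1)))
})

test_that("the M-step applies Laplace smoothing exactly", {
  a <- makeRun("A", c("D1", "D1"), c("G1", "G2"), c(1, 0.5))
  lm <- buildLabelMatrix(list(a))
  ## two objects, p = (1, 0), source labels both true
  prof <- mStep(lm, c(1, 0))
  expect_equal(prof$sensitivity, 2 / 3)
  expect_equal(prof$specificity, 1 / 3)
  ## all p = 0 forces as = 1/2
  expect_equal(mStep(lm, c(0, 0))$sensitivity, 1 / 2)
  ## perfect agreement approaches 1 as n grows
  lmBig <- buildLabelMatrix(list(makeRun("A", rep("D1", 50), paste0("G", 1:50),
                                         seq(1, 0.5, length.out = 50))))
  expect_equal(mStep(lmBig, rep(1, 50))$sensitivity, 51 / 52)
})

test_that("the E-step is the two-class Bayes posterior", {
  lm <- buildLabelMatrix(list(makeRun("A", "D1", "G1", 1),
                              makeRun("B", "D1", "G1", 1)))
  prof <- data.frame(run_id = c("A", "B"), sensitivity = 0.9,
                     specificity = 0.9)
  expect_equal(eStep(lm, prof, 0.5), 0.81 / 0.82)
  ## uninformative sources return the prior
  prof5 <- data.frame(run_id = c("A", "B"), sensitivity = 0.5,
                      specificity = 0.5)
  expect_equal(eStep(lm, prof5, 0.3), 0.3)
  ## two identical sources disagreeing cancel out
  lm2 <- buildLabelMatrix(list(makeRun("A", "D1", "G1", 1),
                               makeRun("B", "D1", "G2", 1)))
  expect_equal(eStep(lm2, prof, 0.5), c(0.5, 0.5))
  ## log-space computation equals the direct product formula at M = 14
  lm14 <- randomLabelMatrix(40, 14, seed = 3)
  set.seed(4)
  prof14 <- data.frame(run_id = sources(lm14),
                       sensitivity = runif(14, 0.55, 0.95),
                       specificity = runif(14, 0.55, 0.95))
  d <- deltaMatrix(lm14)
  A <- apply(d, 1, function(r) prod(ifelse(r == 1, prof14$sensitivity,
                                           1 - prof14$sensitivity)))
  B <- apply(d, 1, function(r) prod(ifelse(r == 1, 1 - prof14$specificity,
                                           prof14$specificity)))
  expect_equal(eStep(lm14, prof14, 0.3), 0.3 * A / (0.3 * A + 0.7 * B),
               tolerance = 1e-12)
})

test_that("runEM matches an independent fixed-point oracle", {
  for (s in 1:4) {
    lm <- randomLabelMatrix(25, 5, seed = 40 + s)
    fit <- runEM(lm, 0.4)
    o <- oracleEM(deltaMatrix(lm), 0.4)
    expect_equal(probabilities(fit), o$p, tolerance = 1e-6)
    expect_equal(sourceProfiles(fit)$sensitivity, o$sensitivity,
                 tolerance = 1e-6)
    expect_equal(sourceProfiles(fit)$specificity, o$specificity,
                 tolerance = 1e-6)
  }
  ## single object, single source: closed-form fixed point agreement
  lm1 <- buildLabelMatrix(list(makeRun("A", "D1", "G1", 1)))
  fit1 <- runEM(lm1, 0.5)
  o1 <- oracleEM(deltaMatrix(lm1), 0.5)
  expect_equal(probabilities(fit1), o1$p, tolerance = 1e-7)
})

test_that("an all-ones matrix drifts to the symmetric fixed point", {
  ## with every source labelling every object positive there is no negative
  ## evidence; "all correct, sensitive sources" and "all wrong,
  ## anti-specific sources" explain the data equally well and EM settles at
  ## p = 1/2 (the independent oracle agrees)
  runs <- lapply(1:3, function(i)
    makeRun(paste0("s", i), rep("D1", 10), paste0("G", 1:10), 10:1))
  lm <- buildLabelMatrix(runs)
  fit <- runEM(lm, 0.5)
  o <- oracleEM(deltaMatrix(lm), 0.5)
  expect_equal(probabilities(fit), o$p, tolerance = 1e-6)
  expect_equal(unique(round(probabilities(fit), 6)), 0.5)
})

test_that("permuting sources permutes profiles and leaves p unchanged", {
  lm <- randomLabelMatrix(30, 6, seed = 77)
  runsOrder <- sources(lm)
  fit <- runEM(lm, 0.3)
  perm <- methods::new("LabelMatrix", objects = labelObjects(lm),
                       sources = rev(sources(lm)),
                       delta = deltaMatrix(lm)[, 6:1])
  fitP <- runEM(perm, 0.3)
  expect_equal(probabilities(fit), probabilities(fitP), tolerance = 1e-9)
  expect_equal(sourceProfiles(fit)$sensitivity,
               rev(sourceProfiles(fitP)$sensitivity), tolerance = 1e-9)
})

test_that("the penalized objective is non-decreasing across iterations", {
  for (s in 1:100) {
    lm <- randomLabelMatrix(sample(5:40, 1), sample(2:8, 1), seed = 500 + s)
    fit <- suppressWarnings(runEM(lm, runif(1, 0.05, 0.95), maxIter = 200))
    expect_true(all(diff(fit@objectiveTrace) >= -1e-9),
                info = paste("seed", 500 + s))
  }
})

test_that("probabilities stay strictly interior after the first E-step", {
  lm <- randomLabelMatrix(50, 14, seed = 9)
  p <- eStep(lm, mStep(lm, initializeProbabilities(lm)), 0.5)
  expect_true(all(p > 0 & p < 1))
})

test_that("with identical profiles p is strictly increasing in vote count", {
  lm <- randomLabelMatrix(60, 8, seed = 10)
  prof <- data.frame(run_id = sources(lm), sensitivity = 0.8,
                     specificity = 0.85)
  p <- eStep(lm, prof, 0.3)
  votes <- rowSums(deltaMatrix(lm))
  agg <- tapply(p, votes, unique)
  expect_true(all(lengths(agg) == 1))
  expect_true(all(diff(unlist(agg)) > 0))
})

test_that("lowering the prior never increases any posterior", {
  lm <- randomLabelMatrix(50, 6, seed = 11)
  prof <- mStep(lm, initializeProbabilities(lm))
  expect_true(all(eStep(lm, prof, 0.01) <= eStep(lm, prof, 0.5)))
})

test_that("silver standard extraction respects the acceptance boundary", {
  a <- makeRun("A", c("D1", "D1", "D2"), c("G1", "G2", "G3"), c(1, 0.9, 1))
  lm <- buildLabelMatrix(list(a))
  fakeFit <- function(p) methods::new(
    "ConsensusResult", p = p,
    profiles = data.frame(run_id = "A", sensitivity = 0.5, specificity = 0.5),
    prior = 0.5, iterations = 1L, converged = TRUE, objectiveTrace = 0)
  s <- annotations(extractSilverStandard(fakeFit(c(0.5, 0.5 - 1e-12, 0.2)), lm))
  expect_equal(s$D1, "G1")            # boundary included, just-below excluded
  expect_equal(s$D2, character())     # all below threshold -> empty set
  expect_error(extractSilverStandard(fakeFit(c(0.5, 0.5)), lm), "aligned")
})

test_that("non-convergence warns and flags instead of failing", {
  lm <- randomLabelMatrix(40, 5, seed = 12)
  expect_warning(fit <- runEM(lm, 0.3, tol = 0, maxIter = 5L),
                 "did not converge")
  expect_false(fit@converged)
  expect_equal(fit@iterations, 5L)
})
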