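## Independent brute-force oracles, deliberately written with plain loops
## and no shared code with the package internals.

## naive TAP-k: enumerate every candidate threshold, recompute all
## precisions from scratch
oracleTap <- function(pred, ann, k) {
  docs <- names(ann)
  cands <- sort(unique(pred$confidence), decreasing = TRUE)
  docRows <- function(d) {
    p <- pred[pred$document_id == d, , drop = FALSE]
    p[order(p$rank), , drop = FALSE]
  }
  fpAt <- function(d, x) {
    p <- docRows(d)
    fp <- 0
    for (i in seq_len(nrow(p)))
      if (p$confidence[i] >= x && !(p$identifier[i] %in% ann[[d]]))
        fp <- fp + 1
    fp
  }
  threshold <- -Inf
  for (x in cands) {
    fps <- vapply(docs, fpAt, numeric(1), x = x)
    if (median(fps) >= k) { threshold <- x; break }
  }
  apcp <- function(d, x) {
    p <- docRows(d)
    gold <- ann[[d]]
    P <- length(gold)
    ret <- which(p$confidence >= x)
    if (P == 0) return(as.numeric(length(ret) == 0))
    if (!length(ret)) return(0)
    tp <- 0; apcSum <- 0; lastPrec <- 0
    for (i in ret) {
      if (p$identifier[i] %in% gold) {
        tp <- tp + 1
        apcSum <- apcSum + tp / i
      }
      lastPrec <- tp / i
    }
    (P * (apcSum / P) + lastPrec) / (P + 1)
  }
  list(threshold = threshold,
       tap = mean(vapply(docs, apcp, numeric(1), x = threshold)))
}

## direct fixed-point EM iteration on a raw 0/1 matrix
oracleEM <- function(delta, prior, tol = 1e-8, maxIter = 1000) {
  M <- ncol(delta)
  p <- rowSums(delta) / M
  for (it in seq_len(maxIter)) {
    as_i <- bs_i <- numeric(M)
    for (i in seq_len(M)) {
      as_i[i] <- (sum(delta[, i] * p) + 1) / (sum(p) + 2)
      bs_i[i] <- (sum((1 - delta[, i]) * (1 - p)) + 1) / (sum(1 - p) + 2)
    }
    pNew <- numeric(nrow(delta))
    for (j in seq_len(nrow(delta))) {
      A <- 1; B <- 1
      for (i in seq_len(M)) {
        if (delta[j, i] == 1) { A <- A * as_i[i]; B <- B * (1 - bs_i[i]) }
        else { A <- A * (1 - as_i[i]); B <- B * bs_i[i] }
      }
      pNew[j] <- prior * A / (prior * A + (1 - prior) * B)
    }
    done <- max(abs(pNew - p)) < tol
    p <- pNew
    if (done) break
  }
  list(p = p, sensitivity = as_i, specificity = bs_i, iterations = it)
}

## exact two-sided signed-rank p-value by enumerating all sign assignments
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  vAll <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vAll[m + 1] <- sum(r[signs == 1])
  }
  pLow <- mean(vAll <= vObs)
  pHigh <- mean(vAll >= vObs)
  min(1, 2 * min(pLow, pHigh))
}

## convenience builders -------------------------------------------------

makeRun <- function(id, document_id, identifier, confidence) {
  newSourceRun(id, data.frame(document_id = document_id,
                              identifier = identifier,
                              confidence = confidence,
                              stringsAsFactors = FALSE))
}

## random small run + gold instance for grid tests
randomInstance <- function(nDocs, maxPreds, seed) {
  set.seed(seed)
  docs <- paste0("D", seq_len(nDocs))
  ids <- paste0("G", 1:8)
  preds <- do.call(rbind, lapply(docs, function(d) {
    np <- sample(0:maxPreds, 1)
    if (!np) return(NULL)
    data.frame(document_id = d,
               identifier = sample(ids, np),
               confidence = round(runif(np), 2),
               stringsAsFactors = FALSE)
  }))
  ann <- lapply(docs, function(d) {
    ng <- sample(0:4, 1)
    if (!ng) character() else sample(ids, ng)
  })
  names(ann) <- docs
  if (is.null(preds))
    preds <- data.frame(document_id = character(), identifier = character(),
                        confidence = numeric())
  list(run = makeRun("rnd", preds$document_id, preds$identifier,
                     preds$confidence),
       gold = newGoldStandard(ann))
}

## random label matrix with at least one positive label per object
randomLabelMatrix <- function(nObj, nSrc, seed, pOne = 0.4) {
  set.seed(seed)
  delta <- matrix(rbinom(nObj * nSrc, 1, pOne), nObj, nSrc)
  zero <- rowSums(delta) == 0
  delta[cbind(which(zero), sample.int(nSrc, sum(zero), replace = TRUE))] <- 1L
  ## every source must label something, or its run would be empty
  zc <- colSums(delta) == 0
  delta[cbind(sample.int(nObj, sum(zc), replace = TRUE), which(zc))] <- 1L
  runs <- lapply(seq_len(nSrc), function(i) {
    j <- which(delta[, i] == 1L)
    makeRun(sprintf("s%02d", i),
            document_id = paste0("D", ((j - 1) %% 5) + 1),
            identifier = paste0("G", j),
            confidence = runif(length(j)))
  })
  buildLabelMatrix(runs)
}
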