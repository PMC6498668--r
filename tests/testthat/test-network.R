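test_that("gene filtering removes low-expression and low-variability genes", {
  # 10 genes with controlled means and CoVs
  set.seed(31)
  n <- 50
  means <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  cvs <- c(0.5, 0.4, 0.01, 0.3, 0.2, 0.02, 0.6, 0.03, 0.25, 0.35)
  mk <- function() {
    sapply(seq_along(means), function(i) rnorm(n, means[i], means[i] * cvs[i]))
  }
  pair <- ExpressionPair(mk(), mk(), geneNames = paste0("g", 1:10))
  pooled <- rbind(exprA(pair), exprB(pair))
  mu <- colMeans(pooled)
  keep1 <- mu > quantile(mu, 0.3, type = 7)
  cv <- apply(pooled[, keep1], 2, sd) / mu[keep1]
  expectNames <- names(which(cv > quantile(cv, 0.7, type = 7)))
  out <- filterGenes(pair, 30, 70)
  expect_equal(geneNames(out), expectNames)
  # a constant gene with high mean survives step 1 but dies at step 2
  pair2 <- ExpressionPair(cbind(exprA(pair), gc = rep(100, n)),
                          cbind(exprB(pair), gc = rep(100, n)))
  expect_false("gc" %in% geneNames(filterGenes(pair2, 30, 70)))
  # raising the expression cutoff never increases survivors
  n30 <- length(geneNames(filterGenes(pair, 30, 70)))
  n60 <- length(geneNames(filterGenes(pair, 60, 70)))
  expect_lte(n60, n30)
})

test_that("joint network inference recovers a strong sparse support", {
  sim <- simulateNetworkPair(p = 3, nEdges = 2, nChanged = 0, n = 500,
                             sigma2Meas = 0.001, seed = 32)
  l1m <- lambda1Max(sim$data)
  net <- inferNetworkPair(sim$data, 0.05 * l1m, 0.01 * l1m)
  expect_true(all(diag(coefA(net)) == 0))
  expect_true(all(diag(coefB(net)) == 0))
  truth <- coefA(sim$truth) != 0
  # every true edge recovered (both directions of the regression may add
  # the reverse edge, so check support coverage, not equality)
  expect_true(all((coefA(net) != 0)[truth]))
})

test_that("strong fusion makes both inferred networks identical", {
  sim <- simulateNetworkPair(p = 6, nEdges = 8, nChanged = 2, n = 40,
                             sigma2Meas = 0.05, seed = 33)
  lam1 <- 0.3 * lambda1Max(sim$data)
  l2m <- lambda2Max(sim$data, lam1)
  net <- inferNetworkPair(sim$data, lam1, l2m)
  expect_lt(max(abs(networkDelta(net))), 1e-6)
})

test_that("separate lasso equals the joint fit at lam2 = 0", {
  sim <- simulateNetworkPair(p = 6, nEdges = 8, nChanged = 2, n = 30,
                             sigma2Meas = 0.05, seed = 34)
  lam1 <- 0.2 * lambda1Max(sim$data)
  sep <- separateLassoPair(sim$data, lam1)
  joint <- inferNetworkPair(sim$data, lam1, 0,
                            control = solverControl(tol = 1e-9))
  expect_true(all(diag(coefA(sep)) == 0))
  # per-gene objective gap between the two routes
  for (i in 1:6) {
    d <- makeDesign(sim$data, i)
    gap <- abs(jointObjective(d, coefA(joint)[-i, i], coefB(joint)[-i, i],
                              lam1, 0) -
                 jointObjective(d, coefA(sep)[-i, i], coefB(sep)[-i, i],
                                lam1, 0))
    expect_lt(gap, 1e-8)
  }
  # beyond the network lambda1Max both baseline networks are empty
  empty <- separateLassoPair(sim$data, 1.01 * lambda1Max(sim$data))
  expect_equal(sum(coefA(empty) != 0) + sum(coefB(empty) != 0), 0)
})

test_that("fusion never increases the number of differing entries", {
  sim <- simulateNetworkPair(p = 6, nEdges = 8, nChanged = 2, n = 30,
                             sigma2Meas = 0.05, seed = 35)
  l1m <- lambda1Max(sim$data)
  for (lam1 in c(0.3, 0.15) * l1m) {
    base <- inferNetworkPair(sim$data, lam1, 0)
    nDiff0 <- sum(networkDelta(base) != 0)
    for (lam2 in c(0.1, 0.5, 2) * lam1) {
      fused <- inferNetworkPair(sim$data, lam1, lam2)
      expect_lte(sum(networkDelta(fused) != 0), nDiff0)
    }
  }
})

test_that("changed-edge criteria combine fold change and magnitude", {
  mk <- function(b, bt) {
    NetworkPair(matrix(c(0, b, 0, 0), 2, 2), matrix(c(0, bt, 0, 0), 2, 2),
                geneNames = c("g1", "g2"))
  }
  expect_true(changedEdges(mk(1.0, 2.1), tThreshold = 0.5)[2, 1])
  expect_false(changedEdges(mk(1.0, 1.5), tThreshold = 0.5)[2, 1]) # < one-fold
  expect_false(changedEdges(mk(0, 0.01), tThreshold = 0.5)[2, 1])  # tiny magnitude
  expect_false(any(changedEdges(mk(1.0, 1.0), tThreshold = 0.5)))  # no change
  # threshold T: 20th percentile of pooled nonzero magnitudes
  net <- NetworkPair(matrix(c(0, 1, 2, 0), 2, 2),
                     matrix(c(0, 3, 4, 0), 2, 2))
  expect_equal(changedThreshold(net, 20),
               as.numeric(quantile(c(1, 2, 3, 4), 0.2, type = 7)))
})

test_that("changed edges are ranked by frequency, then difference magnitude", {
  p <- 3
  genes <- paste0("g", 1:p)
  dr <- matrix(0, p, p, dimnames = list(genes, genes))
  dr[1, 2] <- 0.9; dr[2, 3] <- 0.5; dr[3, 1] <- 0.7
  fr <- new("StabilityFrequencies", r = dr * 0, rTilde = dr * 0, deltaR = dr,
            nRuns = 1L, nPairs = 1L)
  b <- matrix(0, p, p, dimnames = list(genes, genes))
  bt <- b
  b[1, 2] <- 1; b[2, 3] <- 0.5; b[3, 1] <- 2
  net <- NetworkPair(b, bt, geneNames = genes)
  tab <- rankChangedEdges(fr, net)
  expect_equal(nrow(tab), 3) # one row per nonzero frequency
  expect_equal(tab$source, c("g1", "g3", "g2"))
  expect_equal(tab$deltaR, c(0.9, 0.7, 0.5))
  # ties on frequency break by |deltaB|
  dr[1, 2] <- 0.7
  fr2 <- new("StabilityFrequencies", r = dr * 0, rTilde = dr * 0,
             deltaR = dr, nRuns = 1L, nPairs = 1L)
  tab2 <- rankChangedEdges(fr2, net)
  expect_equal(tab2$source[1:2], c("g3", "g1")) # |2| before |1|
})
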