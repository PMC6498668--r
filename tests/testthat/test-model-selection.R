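test_that("two-SE rule selects by hand on a planted error table", {
  lam1 <- c(4, 2, 1)
  lam2 <- rbind(c(3, 1.5, 0.75), c(2, 1, 0.5), c(1.6, 0.8, 0.4))
  pe <- rbind(c(4.8, 8, 7),
              c(6, 3, 4),
              c(5, 4.2, 6))
  se <- matrix(1, 3, 3)
  sel <- twoSESelect(pe, se, lam1, lam2)
  # minimum is 3 at (lam1 = 2, lam2 = 1); threshold 3 + 2*1 = 5
  expect_equal(sel$lam1Min, 2)
  expect_equal(sel$lam2Min, 1)
  # candidates need pe <= 5, lam1 >= 2, lam2 >= 1: that leaves
  # (lam1 = 4, lam2 = 3, pe = 4.8) and the minimiser itself; the rule takes
  # the largest lam1 first
  expect_equal(sel$lam1Opt, 4)
  expect_equal(sel$lam2Opt, 3)
})

test_that("a flat error surface selects the largest penalty pair", {
  lam1 <- c(4, 2)
  lam2 <- rbind(c(3, 1), c(2, 0.5))
  pe <- matrix(5, 2, 2)
  se <- matrix(0, 2, 2)
  sel <- twoSESelect(pe, se, lam1, lam2)
  expect_equal(sel$lam1Opt, 4)
  expect_equal(sel$lam2Opt, 3)
})

test_that("cross-validation partitions every sample into exactly one fold", {
  d <- randomDesign(n = 23, p = 5, seed = 90)
  g <- buildLambdaGrid(d, k1 = 3, k2 = 2)
  cv <- crossValidate(d, g, folds = 5, seed = 7)
  expect_s4_class(cv, "CVResult")
  expect_true(all(cv@pe >= 0))
  expect_gte(cv@lam1Opt, cv@lam1Min)
  expect_gte(cv@lam2Opt, cv@lam2Min)
  # the partition property itself
  set.seed(7)
  f <- jointnet:::foldAssign(23, 5)
  expect_length(f, 23)
  expect_true(all(tabulate(f, 5) %in% c(4, 5)))
  expect_error(crossValidate(randomDesign(n = 4, p = 3, seed = 1), g,
                             folds = 5), "at least")
})

test_that("cross-validation picks penalties that recover a strong signal", {
  d <- randomDesign(n = 60, p = 8, nSignal = 2, sigma = 0.05, seed = 91)
  g <- buildLambdaGrid(d, alpha1 = 0.6952, alpha2 = 0.3728, k1 = 12, k2 = 5)
  cv <- crossValidate(d, g, seed = 8)
  fit <- solveJoint(d, cv@lam1Opt, cv@lam2Opt)
  expect_true(all(which(fit@beta != 0) %in% 1:3) || sum(fit@beta != 0) <= 4)
  expect_true(all(fit@beta[1:2] != 0))
})

test_that("stability frequencies are proportions with zero diagonal", {
  sim <- simulateNetworkPair(p = 6, nEdges = 8, nChanged = 2, n = 24,
                             sigma2Meas = 0.1, seed = 12)
  l1m <- lambda1Max(sim$data)
  pairs <- cbind(c(0.3, 0.15) * l1m, c(0.1, 0.05) * l1m)
  fr <- stabilitySelect(sim$data, pairs, nRuns = 2, seed = 5)
  expect_s4_class(fr, "StabilityFrequencies")
  expect_true(all(edgeFreqA(fr) >= 0 & edgeFreqA(fr) <= 1))
  expect_true(all(changedFreq(fr) >= 0 & changedFreq(fr) <= 1))
  expect_true(all(diag(edgeFreqA(fr)) == 0))
  expect_equal(fr@nPairs, 2L)
})

test_that("a strong planted edge is always selected; N = 1, K = 1 gives r = 1", {
  # one dominant edge g1 -> g2, plenty of samples, little noise
  set.seed(13)
  n <- 120
  x1 <- rnorm(n); x1b <- rnorm(n)
  ya <- 2 * x1 + rnorm(n, sd = 0.05)
  yb <- rnorm(n, sd = 1) # edge absent in condition B
  pair <- ExpressionPair(cbind(g1 = x1, g2 = ya, g3 = rnorm(n)),
                         cbind(g1 = x1b, g2 = yb, g3 = rnorm(n)))
  lam <- 0.15 * lambda1Max(pair)
  fr <- stabilitySelect(pair, cbind(lam, lam / 4), nRuns = 1, seed = 2,
                        applyChangedCriteria = FALSE)
  expect_equal(edgeFreqA(fr)["g1", "g2"], 1) # selected in both halves: 2/2
  expect_equal(changedFreq(fr)["g1", "g2"], 1)
  # with more rounds the planted change still hits frequency 1
  fr5 <- stabilitySelect(pair, cbind(lam, lam / 4), nRuns = 5, seed = 3,
                         applyChangedCriteria = FALSE)
  expect_equal(changedFreq(fr5)["g1", "g2"], 1)
})

test_that("frequencies are stable under within-condition sample relabeling", {
  sim <- simulateNetworkPair(p = 5, nEdges = 6, nChanged = 1, n = 40,
                             sigma2Meas = 0.05, seed = 14)
  lam <- 0.2 * lambda1Max(sim$data)
  fr1 <- stabilitySelect(sim$data, cbind(lam, lam / 3), nRuns = 100,
                         seed = 21, applyChangedCriteria = FALSE)
  perm <- ExpressionPair(exprA(sim$data)[sample(40), ],
                         exprB(sim$data)[sample(40), ],
                         geneNames = geneNames(sim$data))
  fr2 <- stabilitySelect(perm, cbind(lam, lam / 3), nRuns = 100,
                         seed = 22, applyChangedCriteria = FALSE)
  expect_lt(max(abs(edgeFreqA(fr1) - edgeFreqA(fr2))), 0.06)
})

test_that("larger lam1 never increases the expected edge count", {
  sim <- simulateNetworkPair(p = 8, nEdges = 10, nChanged = 2, n = 40,
                             sigma2Meas = 0.05, seed = 15)
  l1m <- lambda1Max(sim$data)
  counts <- vapply(c(0.8, 0.4, 0.2, 0.1) * l1m, function(l1) {
    net <- inferNetworkPair(sim$data, l1, l1 / 4)
    sum(coefA(net) != 0) + sum(coefB(net) != 0)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("frequency thresholding uses a >= boundary", {
  r <- matrix(0, 2, 2); rt <- r
  dr <- matrix(c(0, 0.95, 0.85, 0), 2, 2)
  fr <- new("StabilityFrequencies", r = r, rTilde = rt, deltaR = dr,
            nRuns = 1L, nPairs = 1L)
  sel <- selectEdgesByThreshold(fr, 0.9)
  expect_true(sel$changed[2, 1])
  expect_false(sel$changed[1, 2])
  selB <- selectEdgesByThreshold(fr, 0.85)
  expect_true(selB$changed[1, 2]) # boundary counts as selected
  expect_error(selectEdgesByThreshold(fr, 0), "\\(0, 1\\]")
  expect_error(selectEdgesByThreshold(fr, 1.1), "\\(0, 1\\]")
})
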