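test_that("lambda1Max matches the inner-product formula and scales quadratically", {
  xa <- cbind(p1 = c(1, 0, -1))
  xb <- cbind(p1 = c(0.25, -0.25, 0))
  d <- DesignPair(c(1, -1, 0), xa, c(1, -1, 0), xb, center = FALSE,
                  predictorLabels = "p1")
  # condition A contributes 2|x_j' x_i| = 2; condition B contributes 1
  expect_equal(lambda1Max(d), 2)
  d2 <- DesignPair(2 * c(1, -1, 0), 2 * xa, 2 * c(1, -1, 0), 2 * xb,
                   center = FALSE, predictorLabels = "p1")
  expect_equal(lambda1Max(d2), 4 * lambda1Max(d))
})

test_that("the joint solution is zero exactly at lambda1Max", {
  for (s in 1:10) {
    d <- randomDesign(n = 20, p = 6, seed = 50 + s)
    l1m <- lambda1Max(d)
    at <- solveJoint(d, l1m, 0)
    expect_true(all(at@beta == 0) && all(at@betaTilde == 0))
    below <- solveJoint(d, 0.5 * l1m, 0)
    expect_true(any(below@beta != 0) || any(below@betaTilde != 0))
    # just below lambda1Max only coordinates attaining the max can activate
    just <- solveJoint(d, l1m * (1 - 1e-3), 0,
                       control = solverControl(tol = 1e-10))
    scoreA <- 2 * abs(crossprod(designA(d), responses(d)$a))
    scoreB <- 2 * abs(crossprod(designB(d), responses(d)$b))
    active <- which(just@beta != 0 | just@betaTilde != 0)
    if (length(active)) {
      top <- max(scoreA, scoreB)
      expect_true(all(pmax(scoreA[active], scoreB[active]) > top * 0.99))
    }
  }
})

test_that("the common coefficient vector solves the stacked problem", {
  d <- randomDesign(n = 30, p = 5, seed = 61)
  zs <- rbind(designA(d), designB(d))
  ys <- c(responses(d)$a, responses(d)$b)
  # unpenalized limit: stacked OLS
  expect_equal(unname(commonBetaStar(d, 0)), as.numeric(qr.solve(zs, ys)),
               tolerance = 1e-7)
  # beyond the stacked lambda-max: zero
  expect_equal(unname(commonBetaStar(d, 1.1 * max(abs(crossprod(zs, ys))))),
               rep(0, 5))
  # local optimality against random perturbations
  bs <- commonBetaStar(d, 1.5)
  J <- function(b) jointObjective(d, b, b, 1.5, 0)
  set.seed(62)
  for (i in 1:100) {
    expect_gte(J(bs + rnorm(5, sd = 0.01)), J(bs) - 1e-10)
  }
})

test_that("lambda2Max bounds the fusion point", {
  # exact-fit case with lam1 = 0: residuals vanish, bound is 0
  set.seed(63)
  z <- matrix(rnorm(40), 10, 4)
  b0 <- c(1, -2, 0.5, 0)
  d0 <- DesignPair(as.numeric(z %*% b0), z, as.numeric(z %*% b0), z)
  expect_lt(lambda2Max(d0, 0), 1e-6)
  for (s in 1:10) {
    d <- randomDesign(n = 25, p = 6, seed = 70 + s)
    for (lam1 in c(0.5, 2)) {
      l2m <- lambda2Max(d, lam1)
      expect_gte(l2m, lam1)
      fit <- solveJoint(d, lam1, l2m)
      expect_lt(max(abs(fit@beta - fit@betaTilde)), 1e-6)
    }
  }
})

test_that("geometric penalty grids have exact ratios and sizes", {
  d <- randomDesign(n = 20, p = 5, seed = 80)
  g <- buildLambdaGrid(d, alpha1 = 0.7, alpha2 = 0.8, k1 = 10, k2 = 10)
  expect_length(g@lam1, 10)
  expect_equal(g@lam1[1], lambda1Max(d))
  expect_equal(g@lam1[-1] / g@lam1[-10], rep(0.7, 9))
  for (i in seq_along(g@lam1)) {
    s2 <- g@lam2[[i]]
    expect_length(s2, 10)
    expect_equal(s2[1], lambda2Max(d, g@lam1[i]), tolerance = 1e-8)
    expect_equal(s2[-1] / s2[-10], rep(0.8, 9))
  }
  expect_equal(nrow(lambdaPairs(g)), 100)
  expect_error(buildLambdaGrid(d, alpha1 = 1.2), "decay factors")
})
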