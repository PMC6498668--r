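test_that("column centering removes means and is idempotent", {
  cc <- centerColumns(cbind(c(1, 3)))
  expect_equal(as.numeric(cc$matrix), c(-1, 1))
  expect_equal(cc$means, 2)
  again <- centerColumns(cc$matrix)
  expect_equal(again$matrix, cc$matrix)
  expect_equal(again$means, 0)
  set.seed(1)
  m <- matrix(rnorm(15, mean = 7), 5, 3)
  expect_lt(max(abs(colSums(centerColumns(m)$matrix))), 1e-10)
  expect_error(centerColumns(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("soft thresholding follows its three branches", {
  expect_equal(softThreshold(2.0, 0.5), 1.5)
  expect_equal(softThreshold(-2.0, 0.5), -1.5)
  expect_equal(softThreshold(0.3, 0.5), 0)
  expect_equal(softThreshold(c(-1, 0, 1), 0), c(-1, 0, 1))
  expect_error(softThreshold(1, -0.1), "nonnegative")
})

test_that("paired prox matches its closed-form examples and the numeric oracle", {
  expect_equal(proxPair(1.0, 0.5, 0, 0.3), list(beta = 0.75, betaTilde = 0.75))
  expect_equal(proxPair(2.0, 0.5, 0.2, 0.3), list(beta = 1.5, betaTilde = 0.6))
  expect_equal(proxPair(0, 0, 0.2, 0.3), list(beta = 0, betaTilde = 0))
  expect_equal(proxPair(-2.0, -0.5, 0.2, 0.3),
               list(beta = -1.5, betaTilde = -0.6))
  set.seed(11)
  for (i in 1:50) {
    t <- runif(1, -3, 3); tt <- runif(1, -3, 3)
    l1 <- runif(1, 0, 2); l2 <- runif(1, 0, 2)
    got <- proxPair(t, tt, l1, l2)
    want <- proxOracle(t, tt, l1, l2)
    expect_lt(max(abs(c(got$beta, got$betaTilde) - want)), 1e-6)
  }
})

test_that("smooth-part gradient matches finite differences and known points", {
  d <- randomDesign(n = 12, p = 4, seed = 2)
  g0 <- jointGradient(rep(0, 4), rep(0, 4), d)
  expect_equal(g0, c(-2 * crossprod(designA(d), responses(d)$a),
                     -2 * crossprod(designB(d), responses(d)$b)))
  set.seed(3)
  b <- rnorm(4); bt <- rnorm(4)
  expect_lt(max(abs(jointGradient(b, bt, d) - numericGradient(d, b, bt))),
            1e-5)
  # least-squares stationary point has zero gradient
  bHat <- qr.solve(designA(d), responses(d)$a)
  btHat <- qr.solve(designB(d), responses(d)$b)
  expect_lt(max(abs(jointGradient(bHat, btHat, d))), 1e-8)
})

test_that("step size matches the Lipschitz constant in both modes", {
  d <- DesignPair(c(1, -1), diag(2), c(2, 0), diag(2), center = FALSE,
                  predictorLabels = c("a", "b"))
  expect_equal(stepSize(d, "eigen"), list(step = 0.25, lipschitz = 4))
  expect_equal(stepSize(d, "trace"), list(step = 0.125, lipschitz = 8))
  dd <- randomDesign(n = 6, p = 3, seed = 4)
  L <- 2 * (max(eigen(crossprod(designA(dd)))$values) +
              max(eigen(crossprod(designB(dd)))$values))
  expect_equal(stepSize(dd)$lipschitz, L, tolerance = 1e-8)
  # trace bound never allows a larger step than the eigen bound
  for (s in 1:10) {
    di <- randomDesign(n = 10, p = 5, seed = 100 + s)
    expect_lte(stepSize(di, "trace")$step, stepSize(di, "eigen")$step)
  }
  z <- matrix(0, 4, 2)
  expect_error(
    stepSize(DesignPair(rnorm(4), z, rnorm(4), z, center = FALSE)),
    "no valid step")
})

test_that("joint solver has a non-increasing objective and is init-invariant", {
  for (s in 1:5) {
    d <- randomDesign(n = 30, p = 6, seed = 20 + s)
    fit <- solveJoint(d, lam1 = 1, lam2 = 0.5)
    expect_true(fit@converged)
    expect_true(all(diff(objectivePath(fit)) <= 1e-9))
    # recorded objective agrees with direct evaluation from the data
    expect_equal(jointObjective(d, fit@beta, fit@betaTilde, 1, 0.5),
                 tail(objectivePath(fit), 1), tolerance = 1e-10)
    # convexity: a different start reaches the same objective
    init <- list(beta = rnorm(6), betaTilde = rnorm(6))
    fit2 <- solveJoint(d, 1, 0.5, control = solverControl(tol = 1e-9),
                       init = init)
    expect_lt(abs(tail(objectivePath(fit), 1) - tail(objectivePath(fit2), 1)),
              1e-7)
  }
})

test_that("lam2 = 0 decouples into two lassos (coordinate-descent and glmnet)", {
  library(glmnet)
  for (s in 1:3) {
    d <- randomDesign(n = 40, p = 10, seed = 30 + s)
    lam <- 2
    fit <- solveJoint(d, lam, 0, control = solverControl(tol = 1e-9))
    cdA <- lassoCD(responses(d)$a, designA(d), lam)
    cdB <- lassoCD(responses(d)$b, designB(d), lam)
    expect_lt(abs(jointObjective(d, fit@beta, fit@betaTilde, lam, 0) -
                    jointObjective(d, cdA, cdB, lam, 0)), 1e-8)
    expect_lt(max(abs(fit@beta - glmnetLasso(responses(d)$a, designA(d), lam))),
              1e-4)
  }
})

test_that("solver warns but returns a result when the iteration cap is hit", {
  d <- randomDesign(n = 30, p = 6, seed = 41)
  expect_warning(
    fit <- solveJoint(d, 0.01, 0.005,
                      control = solverControl(tol = 1e-12, maxIter = 3)),
    "did not converge")
  expect_false(fit@converged)
  expect_equal(fit@nIter, 3L)
})

test_that("coordinate-descent lasso hits its closed forms", {
  # orthonormal design: b_j = S(z_j'y, lam * scale / 2)
  set.seed(5)
  q <- qr.Q(qr(matrix(rnorm(24), 6, 4)))
  y <- rnorm(6)
  z <- crossprod(q, y)
  lam <- 0.8
  b <- lassoCD(y, q, lam)
  expect_equal(b, setNames(softThreshold(as.numeric(z), lam / 2), NULL),
               tolerance = 1e-9)
  # lam beyond the lasso lambda-max gives the zero vector
  expect_equal(unname(lassoCD(y, q, 2 * max(abs(z)) + 0.1)), rep(0, 4))
  # unpenalized limit is ordinary least squares
  d <- randomDesign(n = 25, p = 4, seed = 6)
  ols <- qr.solve(designA(d), responses(d)$a)
  expect_equal(unname(lassoCD(responses(d)$a, designA(d), 0)),
               as.numeric(ols), tolerance = 1e-7)
})
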