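# Shared fixtures and independent oracles used across the test files.

# Random small two-condition regression problem with planted sparse signal.
randomDesign <- function(n = 40, p = 8, nSignal = 3, sigma = 0.1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xa <- matrix(rnorm(n * p), n, p)
  xb <- matrix(rnorm(n * p), n, p)
  beta <- rep(0, p); beta[seq_len(nSignal)] <- runif(nSignal, 0.5, 1.5)
  betaT <- beta; if (p >= nSignal + 1) betaT[nSignal + 1] <- 1
  ya <- as.numeric(xa %*% beta) + rnorm(n, sd = sigma)
  yb <- as.numeric(xb %*% betaT) + rnorm(n, sd = sigma)
  DesignPair(ya, xa, yb, xb)
}

# Eq-style joint objective evaluated directly from the data (independent of
# the solver's Gram-form bookkeeping).
jointObjective <- function(design, beta, betaTilde, lam1, lam2) {
  sum((responses(design)$a - designA(design) %*% beta)^2) +
    sum((responses(design)$b - designB(design) %*% betaTilde)^2) +
    lam1 * (sum(abs(beta)) + sum(abs(betaTilde))) +
    lam2 * sum(abs(beta - betaTilde))
}

# Brute-force oracle for the two-variable prox problem: coarse grid scan
# followed by Nelder-Mead refinement from several starts.
proxOracle <- function(t, tTilde, lam1Eff, lam2Eff) {
  f <- function(v) {
    lam1Eff * (abs(v[1]) + abs(v[2])) + lam2Eff * abs(v[1] - v[2]) +
      0.5 * ((v[1] - t)^2 + (v[2] - tTilde)^2)
  }
  starts <- list(c(t, tTilde), c(0, 0),
                 c((t + tTilde) / 2, (t + tTilde) / 2), c(t, 0), c(0, tTilde))
  best <- NULL
  for (s in starts) {
    o <- optim(s, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

# Central finite differences of the smooth objective part.
numericGradient <- function(design, beta, betaTilde, h = 1e-6) {
  g1 <- function(v) {
    b <- v[seq_along(beta)]
    bt <- v[-seq_along(beta)]
    sum((responses(design)$a - designA(design) %*% b)^2) +
      sum((responses(design)$b - designB(design) %*% bt)^2)
  }
  v <- c(beta, betaTilde)
  vapply(seq_along(v), function(j) {
    e <- rep(0, length(v)); e[j] <- h
    (g1(v + e) - g1(v - e)) / (2 * h)
  }, numeric(1))
}

# glmnet reference fit in the no-1/n scaling: lambda_glmnet = lam / (2 n).
glmnetLasso <- function(y, z, lam) {
  fit <- glmnet::glmnet(z, y, lambda = lam / (2 * length(y)),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
  as.numeric(fit$beta)
}
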