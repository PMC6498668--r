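#' @include AllClasses.R
NULL

# sign-flipped Uniform(0, 1] weights, excluding exact zero
signedUnif <- function(k, lo = 0, hi = 1) {
  u <- runif(k, lo, hi)
  u[u == lo] <- (lo + hi) / 2 # guard the open endpoint
  sample(c(-1, 1), k, replace = TRUE) * u
}

#' Simulate a paired sparse linear-regression problem
#'
#' Generates the benchmark regression pair: i.i.d. standard-normal design
#' matrices for both conditions, a sparse coefficient vector \code{beta}
#' with \code{nNonzero} entries drawn uniformly from
#' \eqn{\pm[coefRange_1, coefRange_2]}, and a second vector
#' \code{betaTilde} derived from it by zeroing \code{nZeroed} random
#' nonzero entries and assigning fresh values to \code{nAdded} random zero
#' entries, so exactly \code{nZeroed + nAdded} entries differ.  Responses
#' follow the linear model with N(0, \code{sigma2}) noise.
#'
#' @param n samples per condition (default 100).
#' @param pMinus1 number of predictors (default 200).
#' @param nNonzero nonzero entries of \code{beta} (default 20).
#' @param nZeroed entries of \code{beta} zeroed in \code{betaTilde}
#'   (default 4).
#' @param nAdded zero entries given fresh values in \code{betaTilde}
#'   (default 6).
#' @param coefRange magnitude range of nonzero coefficients
#'   (default c(0.5, 1.5)).
#' @param sigma2 noise variance (default 0.01).
#' @param seed optional seed; identical seeds give identical output.
#' @return list with \code{design} (a centered \linkS4class{DesignPair}),
#'   and the true \code{beta}, \code{betaTilde}.
#' @export
simulateLinearPair <- function(n = 100, pMinus1 = 200, nNonzero = 20,
                               nZeroed = 4, nAdded = 6,
                               coefRange = c(0.5, 1.5), sigma2 = 0.01,
                               seed = NULL) {
  if (nNonzero > pMinus1) stop("nNonzero must be <= pMinus1")
  if (nZeroed > nNonzero) stop("nZeroed must be <= nNonzero")
  if (nAdded > pMinus1 - nNonzero)
    stop("nAdded must be <= pMinus1 - nNonzero")
  withSeed(seed, {
    xa <- matrix(rnorm(n * pMinus1), n, pMinus1)
    xb <- matrix(rnorm(n * pMinus1), n, pMinus1)
    beta <- rep(0, pMinus1)
    nz <- sample(pMinus1, nNonzero)
    beta[nz] <- sample(c(-1, 1), nNonzero, TRUE) *
      runif(nNonzero, coefRange[1], coefRange[2])
    betaT <- beta
    if (nZeroed > 0) betaT[sample(nz, nZeroed)] <- 0
    zeros <- setdiff(seq_len(pMinus1), nz)
    if (nAdded > 0) {
      add <- sample(zeros, nAdded)
      betaT[add] <- sample(c(-1, 1), nAdded, TRUE) *
        runif(nAdded, coefRange[1], coefRange[2])
    }
    ya <- as.numeric(xa %*% beta) + rnorm(n, sd = sqrt(sigma2))
    yb <- as.numeric(xb %*% betaT) + rnorm(n, sd = sqrt(sigma2))
    list(design = DesignPair(ya, xa, yb, xb, targetLabel = "y"),
         beta = beta, betaTilde = betaT)
  })
}

#' Generate a sparse directed network topology
#'
#' Draws a directed adjacency matrix with exactly \code{nEdges} edges, no
#' self-loops, and hub-biased degree heterogeneity: edge sources are
#' sampled with probability proportional to their current out-degree plus
#' one (preferential attachment), targets uniformly.  This emulates the
#' heavy-tailed degree structure of curated regulatory networks.
#'
#' @param p number of genes.
#' @param nEdges number of edges (<= p(p-1)).
#' @param seed optional seed.
#' @return p x p 0/1 adjacency matrix; entry [j, i] = edge j -> i.
#' @export
generateTopology <- function(p, nEdges, seed = NULL) {
  if (nEdges > p * (p - 1)) stop("nEdges exceeds p(p-1) available slots")
  withSeed(seed, {
    a <- matrix(0L, p, p)
    outdeg <- rep(0, p)
    placed <- 0L
    attempts <- 0L
    while (placed < nEdges && attempts < 200L * nEdges) {
      attempts <- attempts + 1L
      src <- sample.int(p, 1, prob = outdeg + 1)
      tgt <- sample.int(p, 1)
      if (tgt == src || a[src, tgt] == 1L) next
      a[src, tgt] <- 1L
      outdeg[src] <- outdeg[src] + 1
      placed <- placed + 1L
    }
    if (placed < nEdges) { # dense corner case: fill remaining slots
      free <- which(a == 0L & row(a) != col(a))
      fill <- sample(free, nEdges - placed)
      a[fill] <- 1L
    }
    a
  })
}

#' Rewire a topology
#'
#' Flips exactly \code{nChanged} uniformly chosen off-diagonal entries of
#' the adjacency matrix (existing edges are deleted, absent ones added),
#' leaving everything else identical.
#'
#' @param a adjacency matrix from \code{\link{generateTopology}}.
#' @param nChanged number of entries to flip.
#' @param seed optional seed.
#' @return the rewired adjacency matrix.
#' @export
perturbTopology <- function(a, nChanged, seed = NULL) {
  p <- nrow(a)
  if (nChanged > p * (p - 1)) stop("nChanged exceeds p(p-1)")
  if (nChanged == 0) return(a)
  withSeed(seed, {
    off <- which(row(a) != col(a))
    flip <- sample(off, nChanged)
    a[flip] <- 1L - a[flip]
    a
  })
}

#' Simulate a paired gene network and its expression data
#'
#' Builds two network topologies (the second a rewiring of the first in
#' \code{nChanged} entries), assigns edge weights uniform on
#' \eqn{\pm(0, 1]} (shared wherever the topologies agree, fresh where they
#' differ), and generates expression by the structural model
#' \eqn{X = E(I - B)^{-1}} with i.i.d. standard-normal \code{E}, plus
#' additive N(0, \code{sigma2Meas}) measurement noise:
#' \eqn{Y = X + V}.  If the larger spectral radius of the weight matrices
#' reaches 0.95, both are rescaled by a common factor to radius 0.9, which
#' keeps \eqn{I - B} safely invertible while preserving shared entries.
#'
#' @param p genes (default 50).
#' @param nEdges edges in the first topology (default 62).
#' @param nChanged rewired entries (default 6).
#' @param n samples per condition (default 100).
#' @param sigma2Meas measurement-noise variance (default 0.05).
#' @param seed optional seed.
#' @param topology,topologyTilde optional externally supplied adjacency
#'   matrices (loader hook); when given, \code{p}/\code{nEdges}/
#'   \code{nChanged} are ignored.
#' @return list with \code{data} (an \linkS4class{ExpressionPair} of noisy
#'   expression \code{Y}, \code{YTilde}), the noise-free \code{x},
#'   \code{xTilde}, the true weight matrices \code{b}, \code{bTilde}
#'   (a \linkS4class{NetworkPair}), and adjacencies \code{a},
#'   \code{aTilde}.
#' @export
simulateNetworkPair <- function(p = 50, nEdges = 62, nChanged = 6,
                                n = 100, sigma2Meas = 0.05, seed = NULL,
                                topology = NULL, topologyTilde = NULL) {
  withSeed(seed, {
    a <- if (is.null(topology)) generateTopology(p, nEdges) else topology
    p <- nrow(a)
    at <- if (is.null(topologyTilde)) perturbTopology(a, nChanged)
          else topologyTilde
    b <- matrix(0, p, p)
    nz <- which(a != 0)
    b[nz] <- signedUnif(length(nz))
    bt <- b
    changedIdx <- which(at != a)
    bt[changedIdx] <- 0
    newEdges <- changedIdx[at[changedIdx] != 0]
    bt[newEdges] <- signedUnif(length(newEdges))
    # keep I - B comfortably invertible; common factor preserves sharing
    rho <- max(abs(eigen(b, only.values = TRUE)$values),
               abs(eigen(bt, only.values = TRUE)$values))
    if (rho >= 0.95) {
      s <- 0.9 / rho
      b <- b * s; bt <- bt * s
    }
    e <- matrix(rnorm(n * p), n, p)
    et <- matrix(rnorm(n * p), n, p)
    x <- e %*% solve(diag(p) - b)
    xt <- et %*% solve(diag(p) - bt)
    y <- x + matrix(rnorm(n * p, sd = sqrt(sigma2Meas)), n, p)
    yt <- xt + matrix(rnorm(n * p, sd = sqrt(sigma2Meas)), n, p)
    genes <- paste0("g", seq_len(p))
    list(data = ExpressionPair(y, yt, geneNames = genes),
         x = x, xTilde = xt,
         truth = NetworkPair(b, bt, geneNames = genes),
         a = a, aTilde = at, e = e, eTilde = et)
  })
}
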