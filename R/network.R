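#' @include lambda.R
NULL

#' Filter genes by expression level and variability
#'
#' Two-step filter used before network inference: genes whose mean
#' expression (pooled over both conditions) is at or below the
#' \code{exprPercentile}-th percentile are removed; then genes whose
#' coefficient of variation (pooled sd / pooled mean) is at or below the
#' \code{covPercentile}-th percentile of the remaining genes are removed.
#' Percentiles use linear interpolation; surviving gene order is preserved.
#'
#' @param pair an \linkS4class{ExpressionPair}.
#' @param exprPercentile percentile cutoff on mean expression (default 30).
#' @param covPercentile percentile cutoff on the CoV (default 70).
#' @return A subsetted \linkS4class{ExpressionPair}.
#' @export
filterGenes <- function(pair, exprPercentile = 30, covPercentile = 70) {
  if (exprPercentile < 0 || exprPercentile > 100 ||
      covPercentile < 0 || covPercentile > 100)
    stop("percentiles must lie in [0, 100]")
  if (nrow(pair@exprA) < 2 || nrow(pair@exprB) < 2)
    stop("need at least 2 samples per condition")
  pooled <- rbind(pair@exprA, pair@exprB)
  mu <- colMeans(pooled)
  keep1 <- mu > pctile(mu, exprPercentile)
  if (!any(keep1)) stop("all genes removed by the expression filter")
  cv <- apply(pooled[, keep1, drop = FALSE], 2, sd) / mu[keep1]
  keep2 <- cv > pctile(cv, covPercentile)
  if (!any(keep2)) stop("all genes removed by the CoV filter")
  idx <- which(keep1)[keep2]
  ExpressionPair(pair@exprA[, idx, drop = FALSE],
                 pair@exprB[, idx, drop = FALSE],
                 geneNames = pair@geneNames[idx])
}

# Shared per-split precomputation: centered matrices and their Grams, so
# that every gene's (p-1)x(p-1) Gram is a slice of one p x p crossproduct.
networkGramCache <- function(pair) {
  xa <- centerColumns(pair@exprA)$matrix
  xb <- centerColumns(pair@exprB)$matrix
  list(Ga = crossprod(xa), Gb = crossprod(xb), na = nrow(xa), nb = nrow(xb))
}

# Fit every gene's joint problem at one or more (lam1, lam2) pairs with
# warm starts along the path.  `pairs` is a k x 2 matrix, lambda1-major.
# Returns a list of NetworkPair, one per row of `pairs`.
fitNetworkPath <- function(pair, pairs, control = solverControl(),
                           cache = NULL) {
  p <- length(pair@geneNames)
  if (p < 2) stop("need at least 2 genes")
  if (is.null(cache)) cache <- networkGramCache(pair)
  pairs <- matrix(as.numeric(pairs), ncol = 2,
                  dimnames = list(NULL, c("lam1", "lam2")))
  k <- nrow(pairs)
  nets <- lapply(seq_len(k), function(.) {
    list(b = matrix(0, p, p), bt = matrix(0, p, p))
  })
  convOK <- matrix(TRUE, k, p)
  for (i in seq_len(p)) {
    Ga <- cache$Ga[-i, -i, drop = FALSE]
    Gb <- cache$Gb[-i, -i, drop = FALSE]
    ca <- cache$Ga[-i, i]
    cb <- cache$Gb[-i, i]
    yty <- cache$Ga[i, i] + cache$Gb[i, i]
    L <- 2 * (max(0, eigen(Ga, symmetric = TRUE, only.values = TRUE)$values[1L]) +
              max(0, eigen(Gb, symmetric = TRUE, only.values = TRUE)$values[1L]))
    if (L <= 0) stop("degenerate (all-zero) expression for gene ", i)
    init <- NULL
    for (k2 in seq_len(k)) {
      fit <- solveJointGram(Ga, ca, Gb, cb, yty, L,
                            pairs[k2, 1], pairs[k2, 2], control,
                            init = init, trackObjective = FALSE,
                            warn = FALSE)
      convOK[k2, i] <- fit@converged
      init <- list(beta = fit@beta, betaTilde = fit@betaTilde)
      nets[[k2]]$b[-i, i] <- fit@beta
      nets[[k2]]$bt[-i, i] <- fit@betaTilde
    }
  }
  lapply(seq_len(k), function(k2) {
    NetworkPair(nets[[k2]]$b, nets[[k2]]$bt, geneNames = pair@geneNames,
                fitInfo = list(converged = convOK[k2, ],
                               lam1 = pairs[k2, 1], lam2 = pairs[k2, 2]))
  })
}

#' Jointly infer the two condition-specific networks
#'
#' Solves the joint sparse regression for every gene i = 1..p (its
#' expression regressed on all other genes in both conditions, with the l1
#' and fused penalties) and assembles the coefficient matrices: column i of
#' each matrix is gene i's coefficient vector, so entry [j, i] is the edge
#' j -> i.  Diagonals are structurally zero.  A gene whose solver run hits
#' the iteration cap is flagged in \code{fitInfo} and the run continues.
#'
#' @param pair an \linkS4class{ExpressionPair}.
#' @param lam1,lam2 nonnegative penalties applied to every gene's problem.
#' @param control see \code{\link{solverControl}}.
#' @return A \linkS4class{NetworkPair}.
#' @examples
#' sim <- simulateNetworkPair(p = 10, nEdges = 12, nChanged = 2, n = 60,
#'                            sigma2Meas = 0.01, seed = 1)
#' net <- inferNetworkPair(sim$data, lam1 = 5, lam2 = 2)
#' net
#' @export
inferNetworkPair <- function(pair, lam1, lam2, control = solverControl()) {
  if (lam1 < 0 || lam2 < 0) stop("penalties must be nonnegative")
  net <- fitNetworkPath(pair, cbind(lam1, lam2), control)[[1]]
  if (!all(net@fitInfo$converged))
    warning(sprintf("%d gene(s) did not converge; see fitInfo(net)",
                    sum(!net@fitInfo$converged)))
  net
}

#' Separate-lasso baseline
#'
#' Infers the two networks independently: one lasso regression per gene per
#' condition with penalty \code{lam1}, the single-condition analogue of the
#' joint problem (\code{lam2 = 0} decouples into exactly these fits).  This
#' is the comparison method in the network benchmark.
#'
#' @param pair an \linkS4class{ExpressionPair}.
#' @param lam1 nonnegative penalty.
#' @param maxSweeps passed to \code{\link{lassoCD}}.
#' @return A \linkS4class{NetworkPair}.
#' @export
separateLassoPair <- function(pair, lam1, maxSweeps = 100000L) {
  p <- length(pair@geneNames)
  if (p < 2) stop("need at least 2 genes")
  cache <- networkGramCache(pair)
  b <- matrix(0, p, p); bt <- matrix(0, p, p)
  for (i in seq_len(p)) {
    ra <- cpp_lasso_cd(cache$Ga[-i, -i, drop = FALSE], cache$Ga[-i, i],
                       lam1, rep(0, p - 1), 1e-8, as.integer(maxSweeps))
    rb <- cpp_lasso_cd(cache$Gb[-i, -i, drop = FALSE], cache$Gb[-i, i],
                       lam1, rep(0, p - 1), 1e-8, as.integer(maxSweeps))
    b[-i, i] <- ra$b
    bt[-i, i] <- rb$b
  }
  NetworkPair(b, bt, geneNames = pair@geneNames,
              fitInfo = list(lam1 = lam1, method = "separate-lasso"))
}

#' Magnitude threshold for the changed-edge criteria
#'
#' The \code{tPercentile}-th percentile of all nonzero coefficient
#' magnitudes pooled over both networks; recomputed per analysis.
#'
#' @param net a \linkS4class{NetworkPair}.
#' @param tPercentile percentile in [0, 100] (default 20).
#' @return nonnegative scalar (0 when both networks are empty).
#' @export
changedThreshold <- function(net, tPercentile = 20) {
  vals <- c(abs(net@b[net@b != 0]), abs(net@bTilde[net@bTilde != 0]))
  if (!length(vals)) return(0)
  pctile(vals, tPercentile)
}

#' Call changed regulatory effects between the two networks
#'
#' An edge j -> i is called changed when (i) the difference shows at least
#' a one-fold change relative to the smaller magnitude,
#' \eqn{|\tilde b - b| \ge \min\{|\tilde b|, |b|\}}, and (ii) the larger
#' magnitude clears the threshold, \eqn{\max\{|\tilde b|, |b|\} \ge T};
#' entries with zero difference are never called.  \code{T} defaults to
#' \code{\link{changedThreshold}} of the fitted networks.
#'
#' @param net a \linkS4class{NetworkPair}.
#' @param tThreshold magnitude threshold T (>= 0); computed from
#'   \code{tPercentile} when \code{NULL}.
#' @param tPercentile percentile used when \code{tThreshold} is NULL.
#' @return logical p x p matrix (diagonal \code{FALSE}).
#' @export
changedEdges <- function(net, tThreshold = NULL, tPercentile = 20) {
  if (is.null(tThreshold)) tThreshold <- changedThreshold(net, tPercentile)
  if (tThreshold < 0) stop("tThreshold must be >= 0")
  ab <- abs(net@b); abt <- abs(net@bTilde)
  d <- net@bTilde - net@b
  mask <- (abs(d) >= pmin(ab, abt)) & (pmax(ab, abt) >= tThreshold) &
    (d != 0)
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(net@b)
  mask
}

#' Rank changed edges by stability frequency
#'
#' Edges with nonzero changed-edge frequency are sorted by frequency
#' (descending), ties broken by the magnitude of the coefficient difference
#' (descending), then by source and target label.
#'
#' @param freqs a \linkS4class{StabilityFrequencies}.
#' @param net a \linkS4class{NetworkPair} providing the coefficients
#'   reported alongside the ranking.
#' @return data.frame with columns \code{source}, \code{target}, \code{b},
#'   \code{bTilde}, \code{deltaB}, \code{deltaR}.
#' @export
rankChangedEdges <- function(freqs, net) {
  if (!all(dim(freqs@deltaR) == dim(net@b)))
    stop("frequency and network dimensions differ")
  idx <- which(freqs@deltaR > 0, arr.ind = TRUE)
  genes <- net@geneNames
  out <- data.frame(
    source = genes[idx[, 1]], target = genes[idx[, 2]],
    b = net@b[idx], bTilde = net@bTilde[idx],
    deltaB = net@b[idx] - net@bTilde[idx],
    deltaR = freqs@deltaR[idx],
    stringsAsFactors = FALSE)
  ord <- order(-out$deltaR, -abs(out$deltaB), out$source, out$target)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
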