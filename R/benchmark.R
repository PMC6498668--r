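#' @include selection.R simulate.R evaluate.R
NULL

# One-dimensional lasso cross-validation with the two-SE rule, used for the
# separate-lasso baseline (each condition tuned on its own).
cvLassoTwoSE <- function(y, z, folds = 5, alpha = 0.6952, k = 20,
                         seed = NULL) {
  lmax <- 2 * max(abs(crossprod(z, y)))
  lams <- lmax * alpha^(seq_len(k) - 1)
  n <- length(y)
  withSeed(seed, {
    fa <- foldAssign(n, folds)
    foldErr <- t(vapply(seq_len(folds), function(f) {
      te <- which(fa == f); tr <- setdiff(seq_len(n), te)
      cm <- colMeans(z[tr, , drop = FALSE]); rm <- mean(y[tr])
      ztr <- sweep(z[tr, , drop = FALSE], 2, cm); ytr <- y[tr] - rm
      zte <- sweep(z[te, , drop = FALSE], 2, cm); yte <- y[te] - rm
      init <- NULL
      vapply(lams, function(l) {
        b <- lassoCD(ytr, ztr, l, init = init)
        init <<- b
        sum((yte - zte %*% b)^2)
      }, numeric(1))
    }, numeric(k)))
    pe <- colMeans(foldErr)
    se <- apply(foldErr, 2, sd) / sqrt(folds)
    iMin <- which(pe == min(pe))[1]
    thr <- pe[iMin] + 2 * se[iMin]
    iOpt <- which(pe <= thr & lams >= lams[iMin])
    iOpt <- iOpt[which.max(lams[iOpt])]
    list(lambda = lams[iOpt], lambdaMin = lams[iMin], pe = pe, se = se)
  })
}

#' Paired linear-regression benchmark
#'
#' Reproduces the regression-pair simulation protocol: for each replicate a
#' paired sparse regression problem is generated
#' (\code{\link{simulateLinearPair}}), penalties are chosen by five-fold
#' cross-validation with the two-SE rule over a geometric grid (the CV
#' defaults \code{alpha1 = 0.6952, alpha2 = 0.3728, k1 = 20, k2 = 8}), the
#' joint model is refitted on the full data, and nonzero masks of
#' \code{beta}, \code{betaTilde} and their difference are scored against
#' the truth.  The separate-lasso baseline fits each condition's lasso
#' with its own cross-validated penalty on the same data.  Counts are
#' pooled over replicates.
#'
#' @param nReps replicates (default 10).
#' @param n,pMinus1,sigma2 generator settings (defaults 100, 200, 0.01).
#' @param seed master seed; all replicate seeds derive from it.
#' @param folds CV folds (default 5).
#' @param alpha1,alpha2,k1,k2 CV grid settings.
#' @param control see \code{\link{solverControl}}.
#' @return list with \linkS4class{DetectionStats} for the joint method
#'   (\code{joint$beta}, \code{joint$betaTilde}, \code{joint$delta}) and
#'   the baseline (\code{separate$...}), plus a per-replicate summary
#'   data.frame.
#' @export
runLinearBenchmark <- function(nReps = 10, n = 100, pMinus1 = 200,
                               sigma2 = 0.01, seed = 1, folds = 5,
                               alpha1 = 0.6952, alpha2 = 0.3728,
                               k1 = 20, k2 = 8,
                               control = solverControl()) {
  acc <- function() list(est = logical(0), tru = logical(0))
  keys <- c("beta", "betaTilde", "delta")
  joint <- setNames(lapply(keys, function(.) acc()), keys)
  sep <- setNames(lapply(keys, function(.) acc()), keys)
  add <- function(slot, est, tru) {
    slot$est <- c(slot$est, est); slot$tru <- c(slot$tru, tru); slot
  }
  perRep <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    sim <- simulateLinearPair(n = n, pMinus1 = pMinus1, sigma2 = sigma2,
                              seed = childSeed(seed, r))
    des <- sim$design
    grid <- buildLambdaGrid(des, alpha1 = alpha1, alpha2 = alpha2,
                            k1 = k1, k2 = k2)
    cv <- crossValidate(des, grid, folds = folds,
                        seed = childSeed(seed, 1000 + r), control = control)
    fit <- solveJoint(des, cv@lam1Opt, cv@lam2Opt, control = control)
    jb <- fit@beta != 0; jbt <- fit@betaTilde != 0
    jd <- (fit@beta - fit@betaTilde) != 0
    joint$beta <- add(joint$beta, jb, sim$beta != 0)
    joint$betaTilde <- add(joint$betaTilde, jbt, sim$betaTilde != 0)
    joint$delta <- add(joint$delta, jd, sim$beta != sim$betaTilde)
    cvA <- cvLassoTwoSE(des@responseA, des@designA, folds = folds,
                        seed = childSeed(seed, 2000 + r))
    cvB <- cvLassoTwoSE(des@responseB, des@designB, folds = folds,
                        seed = childSeed(seed, 3000 + r))
    bA <- lassoCD(des@responseA, des@designA, cvA$lambda)
    bB <- lassoCD(des@responseB, des@designB, cvB$lambda)
    sep$beta <- add(sep$beta, bA != 0, sim$beta != 0)
    sep$betaTilde <- add(sep$betaTilde, bB != 0, sim$betaTilde != 0)
    sep$delta <- add(sep$delta, (bA - bB) != 0, sim$beta != sim$betaTilde)
    perRep[[r]] <- data.frame(
      rep = r, lam1 = cv@lam1Opt, lam2 = cv@lam2Opt,
      jointDeltaTP = sum(jd & (sim$beta != sim$betaTilde)),
      jointDeltaFP = sum(jd & (sim$beta == sim$betaTilde)))
  }
  stats <- function(x) detectionStats(x$est, x$tru)
  list(joint = lapply(joint, stats), separate = lapply(sep, stats),
       perRep = do.call(rbind, perRep))
}

#' Paired gene-network benchmark
#'
#' Reproduces the network simulation protocol: for each replicate a paired
#' network with \code{nEdges} edges and \code{nChanged} rewired entries is
#' generated (\code{\link{simulateNetworkPair}}), a network-level penalty
#' grid is built with the stability-selection defaults, and changed edges
#' are ranked by stability-selection frequency for both the joint method
#' and the separate-lasso baseline (which uses the \code{lam1} values of
#' the same grid).  Changed-edge rankings are scored against the entries
#' where the true weight matrices differ, pooled over replicates
#' (\code{\link{pooledPR}}); per-replicate AUPRs are also returned for
#' paired comparisons.
#'
#' @param nReps replicates (default 10).
#' @param p,nEdges,nChanged,n,sigma2Meas generator settings (defaults 50,
#'   62, 6, 100, 0.05).
#' @param seed master seed.
#' @param nRuns stability-selection subsample rounds per penalty pair
#'   (default 3).
#' @param alpha1,alpha2,k1,k2 stability grid settings (defaults 0.7, 0.8,
#'   10, 10).
#' @param control see \code{\link{solverControl}}.
#' @return list with pooled \linkS4class{PRResult}s (\code{joint},
#'   \code{separate}) and a per-replicate AUPR data.frame.
#' @export
runNetworkBenchmark <- function(nReps = 10, p = 50, nEdges = 62,
                                nChanged = 6, n = 100, sigma2Meas = 0.05,
                                seed = 1, nRuns = 3,
                                alpha1 = 0.7, alpha2 = 0.8,
                                k1 = 10, k2 = 10,
                                control = solverControl()) {
  scoresJ <- scoresS <- truths <- vector("list", nReps)
  perRep <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    sim <- simulateNetworkPair(p = p, nEdges = nEdges, nChanged = nChanged,
                               n = n, sigma2Meas = sigma2Meas,
                               seed = childSeed(seed, r))
    truth <- networkDelta(sim$truth) != 0
    diag(truth) <- FALSE
    grid <- buildLambdaGrid(sim$data, alpha1 = alpha1, alpha2 = alpha2,
                            k1 = k1, k2 = k2)
    freqJ <- stabilitySelect(sim$data, lambdaPairs(grid), nRuns = nRuns,
                             seed = childSeed(seed, 1000 + r),
                             applyChangedCriteria = FALSE,
                             control = control)
    freqS <- stabilitySelect(sim$data, grid@lam1, nRuns = nRuns,
                             seed = childSeed(seed, 2000 + r),
                             method = "separate",
                             applyChangedCriteria = FALSE)
    scoresJ[[r]] <- changedFreq(freqJ)
    scoresS[[r]] <- changedFreq(freqS)
    truths[[r]] <- truth
    perRep[[r]] <- data.frame(
      rep = r,
      auprJoint = aupr(pooledPR(scoresJ[[r]], truth)),
      auprSeparate = aupr(pooledPR(scoresS[[r]], truth)))
  }
  list(joint = pooledPR(scoresJ, truths),
       separate = pooledPR(scoresS, truths),
       perRep = do.call(rbind, perRep))
}
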