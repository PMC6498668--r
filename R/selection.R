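#' @include network.R
NULL

#' Two-standard-error penalty selection
#'
#' Given matrices of mean prediction error and its standard error over a
#' (lambda1, lambda2) grid, finds the minimiser (ties resolved towards the
#' largest penalties) and then the two-SE choice: among grid points whose
#' error is within two standard errors (taken at the minimiser) of the
#' minimum and whose penalties are at least the minimisers', the largest
#' \code{lam1} is chosen first, then the largest \code{lam2}.
#'
#' @param pe k1 x k2 matrix of mean prediction errors (rows follow
#'   \code{lam1}, columns the per-row \code{lam2} sequences).
#' @param se matching matrix of standard errors.
#' @param lam1 length-k1 vector of lambda1 values (decreasing).
#' @param lam2 k1 x k2 matrix of lambda2 values (row r is the lam2 sequence
#'   for \code{lam1[r]}, decreasing).
#' @return list with \code{lam1Min}, \code{lam2Min}, \code{lam1Opt},
#'   \code{lam2Opt} and the index pairs \code{minIndex}, \code{optIndex}.
#' @export
twoSESelect <- function(pe, se, lam1, lam2) {
  stopifnot(all(dim(pe) == dim(se)), nrow(pe) == length(lam1),
            all(dim(pe) == dim(lam2)))
  peMin <- min(pe)
  cand <- which(pe == peMin, arr.ind = TRUE)
  # tie-break the minimiser towards the largest penalties
  o <- order(-lam1[cand[, 1]], -lam2[cand])
  minIdx <- cand[o[1], , drop = TRUE]
  thr <- peMin + 2 * se[minIdx[1], minIdx[2]]
  lam1Min <- lam1[minIdx[1]]
  lam2Min <- lam2[minIdx[1], minIdx[2]]
  ok <- which(pe <= thr & lam2 >= lam2Min &
                matrix(lam1, nrow(pe), ncol(pe)) >= lam1Min,
              arr.ind = TRUE)
  o <- order(-lam1[ok[, 1]], -lam2[ok])
  optIdx <- ok[o[1], , drop = TRUE]
  list(lam1Min = lam1Min, lam2Min = lam2Min,
       lam1Opt = lam1[optIdx[1]], lam2Opt = lam2[optIdx[1], optIdx[2]],
       minIndex = minIdx, optIndex = optIdx)
}

# Per-condition fold assignment: every sample lands in exactly one fold.
foldAssign <- function(n, folds) sample(rep(seq_len(folds), length.out = n))

#' Cross-validate the penalty pair
#'
#' Five-fold (by default) cross-validation of the joint solver over a
#' \linkS4class{LambdaGrid}.  Samples of each condition are partitioned
#' into folds independently; for each fold the model is fitted on the
#' remaining samples (re-centered) with warm starts along the grid, and
#' the held-out squared error summed over both conditions is recorded.
#' The prediction error at each grid point is the mean over folds, its SE
#' the standard deviation over folds divided by \code{sqrt(folds)}; the
#' penalty pair is selected by \code{\link{twoSESelect}}.
#'
#' The \linkS4class{ExpressionPair} method pools the held-out error over
#' all genes' regressions, selecting one penalty pair for the whole
#' network.
#'
#' @param object a \linkS4class{DesignPair} or \linkS4class{ExpressionPair}.
#' @param grid a \linkS4class{LambdaGrid}.
#' @param folds number of folds (>= 2; each condition needs >= folds
#'   samples).
#' @param seed optional seed controlling the fold assignment.
#' @param control see \code{\link{solverControl}}.
#' @return A \linkS4class{CVResult}.
#' @export
setGeneric("crossValidate",
  function(object, grid, folds = 5, seed = NULL,
           control = solverControl()) standardGeneric("crossValidate"))

# held-out error for one fold of one gene's problem, all grid pairs
cvFoldError <- function(ya, xa, yb, xb, teA, teB, pairs, control) {
  trA <- setdiff(seq_along(ya), teA)
  trB <- setdiff(seq_along(yb), teB)
  # centre with training means only
  cmA <- colMeans(xa[trA, , drop = FALSE]); rmA <- mean(ya[trA])
  cmB <- colMeans(xb[trB, , drop = FALSE]); rmB <- mean(yb[trB])
  ztA <- sweep(xa[trA, , drop = FALSE], 2, cmA); yAtr <- ya[trA] - rmA
  ztB <- sweep(xb[trB, , drop = FALSE], 2, cmB); yBtr <- yb[trB] - rmB
  zeA <- sweep(xa[teA, , drop = FALSE], 2, cmA); yAte <- ya[teA] - rmA
  zeB <- sweep(xb[teB, , drop = FALSE], 2, cmB); yBte <- yb[teB] - rmB
  Ga <- crossprod(ztA); Gb <- crossprod(ztB)
  ca <- as.numeric(crossprod(ztA, yAtr)); cb <- as.numeric(crossprod(ztB, yBtr))
  yty <- sum(yAtr^2) + sum(yBtr^2)
  L <- 2 * (largestGramEigenvalue(ztA) + largestGramEigenvalue(ztB))
  err <- numeric(nrow(pairs))
  init <- NULL
  for (k in seq_len(nrow(pairs))) {
    fit <- solveJointGram(Ga, ca, Gb, cb, yty, L, pairs[k, 1], pairs[k, 2],
                          control, init = init, trackObjective = FALSE,
                          warn = FALSE)
    init <- list(beta = fit@beta, betaTilde = fit@betaTilde)
    err[k] <- sum((yAte - zeA %*% fit@beta)^2) +
      sum((yBte - zeB %*% fit@betaTilde)^2)
  }
  err
}

cvFinish <- function(foldErr, grid) {
  # foldErr: folds x K matrix of held-out errors, K in lambda1-major order
  k1 <- length(grid@lam1); k2 <- length(grid@lam2[[1]])
  pe <- matrix(colMeans(foldErr), k1, k2, byrow = TRUE)
  se <- matrix(apply(foldErr, 2, sd) / sqrt(nrow(foldErr)), k1, k2,
               byrow = TRUE)
  lam2m <- do.call(rbind, grid@lam2)
  sel <- twoSESelect(pe, se, grid@lam1, lam2m)
  new("CVResult", pe = pe, se = se,
      lam1Min = sel$lam1Min, lam2Min = sel$lam2Min,
      lam1Opt = sel$lam1Opt, lam2Opt = sel$lam2Opt, grid = grid)
}

#' @rdname crossValidate
#' @export
setMethod("crossValidate", "DesignPair",
  function(object, grid, folds = 5, seed = NULL,
           control = solverControl()) {
    folds <- as.integer(folds)
    if (folds < 2) stop("folds must be >= 2")
    nA <- length(object@responseA); nB <- length(object@responseB)
    if (nA < folds || nB < folds)
      stop("each condition needs at least 'folds' samples")
    pairs <- lambdaPairs(grid)
    withSeed(seed, {
      fA <- foldAssign(nA, folds); fB <- foldAssign(nB, folds)
      foldErr <- t(vapply(seq_len(folds), function(f) {
        cvFoldError(object@responseA, object@designA,
                    object@responseB, object@designB,
                    which(fA == f), which(fB == f), pairs, control)
      }, numeric(nrow(pairs))))
      cvFinish(foldErr, grid)
    })
  })

#' @rdname crossValidate
#' @export
setMethod("crossValidate", "ExpressionPair",
  function(object, grid, folds = 5, seed = NULL,
           control = solverControl()) {
    folds <- as.integer(folds)
    if (folds < 2) stop("folds must be >= 2")
    nA <- nrow(object@exprA); nB <- nrow(object@exprB)
    if (nA < folds || nB < folds)
      stop("each condition needs at least 'folds' samples")
    pairs <- lambdaPairs(grid)
    p <- length(object@geneNames)
    withSeed(seed, {
      fA <- foldAssign(nA, folds); fB <- foldAssign(nB, folds)
      foldErr <- t(vapply(seq_len(folds), function(f) {
        tot <- numeric(nrow(pairs))
        for (i in seq_len(p)) {
          tot <- tot + cvFoldError(
            object@exprA[, i], object@exprA[, -i, drop = FALSE],
            object@exprB[, i], object@exprB[, -i, drop = FALSE],
            which(fA == f), which(fB == f), pairs, control)
        }
        tot
      }, numeric(nrow(pairs))))
      cvFinish(foldErr, grid)
    })
  })

#' Stability selection over half-sample refits
#'
#' For each penalty pair, each condition's samples are repeatedly split
#' into two halves (independently per condition; with odd counts the first
#' half gets the extra sample) and the full network pair is refitted on
#' each half.  Edge frequencies \code{r}, \code{rTilde} count how often a
#' coefficient is nonzero across all 2NK refits; \code{deltaR} counts how
#' often its between-condition difference qualifies as changed.  By
#' default the changed-edge magnitude criteria
#' (\code{\link{changedEdges}}) are applied within every refit; set
#' \code{applyChangedCriteria = FALSE} to count any nonzero difference
#' (the convention of the simulation benchmark).
#'
#' @param pair an \linkS4class{ExpressionPair}.
#' @param pairs penalty pairs: a k x 2 matrix (columns lam1, lam2) for
#'   \code{method = "joint"}, or a vector of lam1 values for
#'   \code{method = "separate"} (the lasso baseline).
#' @param nRuns number of subsample rounds N (default 50).
#' @param seed optional seed; all splits derive from it.
#' @param method \code{"joint"} or \code{"separate"}.
#' @param applyChangedCriteria apply the fold-change/magnitude criteria
#'   within each refit (default \code{TRUE}).
#' @param tPercentile percentile for the magnitude threshold T.
#' @param control see \code{\link{solverControl}}.
#' @return A \linkS4class{StabilityFrequencies}.
#' @export
stabilitySelect <- function(pair, pairs, nRuns = 50, seed = NULL,
                            method = c("joint", "separate"),
                            applyChangedCriteria = TRUE,
                            tPercentile = 20,
                            control = solverControl()) {
  method <- match.arg(method)
  nRuns <- as.integer(nRuns)
  if (nRuns < 1) stop("nRuns must be >= 1")
  nA <- nrow(pair@exprA); nB <- nrow(pair@exprB)
  if (nA < 4 || nB < 4) stop("each condition needs at least 4 samples")
  if (method == "joint") {
    pairs <- matrix(as.numeric(pairs), ncol = 2)
  } else {
    pairs <- cbind(as.numeric(pairs), 0)
  }
  K <- nrow(pairs)
  p <- length(pair@geneNames)
  m <- mt <- dm <- matrix(0, p, p)
  countNet <- function(net) {
    m <<- m + (net@b != 0)
    mt <<- mt + (net@bTilde != 0)
    dm <<- dm + if (applyChangedCriteria) {
      changedEdges(net, tPercentile = tPercentile)
    } else {
      d <- networkDelta(net); diag(d) <- 0
      d != 0
    }
  }
  withSeed(seed, {
    for (r in seq_len(nRuns)) {
      # independent half-splits per condition; first half gets any extra
      idxA <- sample(nA); idxB <- sample(nB)
      hA <- list(idxA[seq_len(ceiling(nA / 2))],
                 idxA[(ceiling(nA / 2) + 1):nA])
      hB <- list(idxB[seq_len(ceiling(nB / 2))],
                 idxB[(ceiling(nB / 2) + 1):nB])
      for (h in 1:2) {
        half <- ExpressionPair(pair@exprA[hA[[h]], , drop = FALSE],
                               pair@exprB[hB[[h]], , drop = FALSE],
                               geneNames = pair@geneNames)
        if (method == "joint") {
          nets <- fitNetworkPath(half, pairs, control)
          lapply(nets, countNet)
        } else {
          for (k in seq_len(K))
            countNet(separateLassoPair(half, pairs[k, 1]))
        }
      }
    }
  })
  denom <- 2 * nRuns * K
  gn <- list(pair@geneNames, pair@geneNames)
  r <- m / denom; rt <- mt / denom; dr <- dm / denom
  dimnames(r) <- dimnames(rt) <- dimnames(dr) <- gn
  new("StabilityFrequencies", r = r, rTilde = rt, deltaR = dr,
      nRuns = nRuns, nPairs = as.integer(K))
}

#' Threshold stability frequencies into edge calls
#'
#' An edge (or changed edge) is called when its frequency is at least
#' \code{c}; the boundary counts as selected.  Recommended thresholds lie
#' in [0.6, 0.9]; real-data analyses typically use \code{c = 0.9}.
#'
#' @param freqs a \linkS4class{StabilityFrequencies}.
#' @param c selection threshold in (0, 1].
#' @return list of logical matrices \code{edges}, \code{edgesTilde},
#'   \code{changed}.
#' @export
selectEdgesByThreshold <- function(freqs, c = 0.9) {
  if (length(c) != 1L || !is.finite(c) || c <= 0 || c > 1)
    stop("'c' must lie in (0, 1]")
  list(edges = freqs@r >= c,
       edgesTilde = freqs@rTilde >= c,
       changed = freqs@deltaR >= c)
}
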