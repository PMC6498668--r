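#' @include AllClasses.R
NULL

#' Centre the columns of a matrix
#'
#' Removes each column's mean, the operation that absorbs the per-gene
#' intercepts of the network regression model.
#'
#' @param m numeric matrix (samples x features) with at least 2 rows.
#' @return list with \code{matrix} (centered) and \code{means} (the removed
#'   column means).
#' @examples
#' centerColumns(cbind(c(1, 3)))  # column becomes (-1, 1), mean 2
#' @export
centerColumns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to centre")
  stopIfNotFinite(m, "matrix")
  means <- colMeans(m)
  list(matrix = sweep(m, 2, means, "-"), means = means)
}

#' Soft-thresholding operator
#'
#' \code{S(x, a)} shrinks \code{x} towards zero by \code{a}, clipping to
#' zero on \code{[-a, a]}; the scalar proximal operator of the l1 penalty.
#'
#' @param x numeric vector.
#' @param a nonnegative threshold.
#' @return numeric vector of the same length.
#' @examples
#' softThreshold(c(2, -2, 0.3), 0.5)  # 1.5, -1.5, 0
#' @export
softThreshold <- function(x, a) {
  if (length(a) != 1L || !is.finite(a) || a < 0)
    stop("'a' must be a single nonnegative number")
  sign(x) * pmax(abs(x) - a, 0)
}

#' Closed-form prox of the paired fused-lasso penalty
#'
#' Exact minimiser of the two-variable problem
#' \deqn{\lambda_1'(|b|+|\tilde b|) + \lambda_2'|b-\tilde b| +
#'       \tfrac12\{(b-t)^2 + (\tilde b-\tilde t)^2\}}
#' obtained by first fusing the pair (midpoint when
#' \eqn{|t-\tilde t| \le 2\lambda_2'}, otherwise moving each by
#' \eqn{\lambda_2'} towards the other) and then soft-thresholding both
#' components by \eqn{\lambda_1'}.  Vectorised over coordinate pairs; this
#' is the per-coordinate step of the proximal gradient solver, where the
#' effective penalties are \eqn{\lambda_k' = \lambda_k \cdot} step.
#'
#' @param t,tTilde numeric vectors (gradient-step points), equal length.
#' @param lam1Eff,lam2Eff nonnegative effective penalties.
#' @return list with numeric vectors \code{beta} and \code{betaTilde}.
#' @examples
#' proxPair(1, 0.5, 0, 0.3)        # fused midpoint (0.75, 0.75)
#' proxPair(2, 0.5, 0.2, 0.3)      # (1.5, 0.6)
#' @export
proxPair <- function(t, tTilde, lam1Eff, lam2Eff) {
  if (length(t) != length(tTilde)) stop("t and tTilde lengths differ")
  if (lam1Eff < 0 || lam2Eff < 0) stop("effective penalties must be >= 0")
  out <- cpp_prox_pair(as.numeric(t), as.numeric(tTilde),
                       lam1Eff, lam2Eff)
  list(beta = out[, 1], betaTilde = out[, 2])
}

#' Gradient of the smooth part of the joint objective
#'
#' The smooth part is the sum of both conditions' residual sums of squares;
#' its gradient is the stacked vector
#' \code{c(2 (Xa'Xa b - Xa'ya), 2 (Xb'Xb bt - Xb'yb))}.
#'
#' @param beta,betaTilde coefficient vectors (length p - 1).
#' @param design a \linkS4class{DesignPair}.
#' @return numeric vector of length 2(p - 1).
#' @export
jointGradient <- function(beta, betaTilde, design) {
  p <- ncol(design@designA)
  if (length(beta) != p || length(betaTilde) != p)
    stop("coefficient length must match the design column count")
  ga <- 2 * (crossprod(design@designA, design@designA %*% beta) -
               crossprod(design@designA, design@responseA))
  gb <- 2 * (crossprod(design@designB, design@designB %*% betaTilde) -
               crossprod(design@designB, design@responseB))
  c(as.numeric(ga), as.numeric(gb))
}

#' Step size and Lipschitz constant for the proximal gradient iteration
#'
#' In \code{"eigen"} mode the Lipschitz constant of the smooth gradient is
#' \eqn{L = 2(\gamma + \tilde\gamma)} with \eqn{\gamma,\tilde\gamma} the
#' largest eigenvalues of the two Gram matrices, computed on the smaller of
#' the n x n / (p-1) x (p-1) Gram forms.  In \code{"trace"} mode the traces
#' replace the eigenvalues: cheaper, always at least as large, hence a step
#' that is never larger.  The step is constant across iterations.
#'
#' @param design a \linkS4class{DesignPair}.
#' @param mode \code{"eigen"} (default) or \code{"trace"}.
#' @return list with \code{step} (= 1/L) and \code{lipschitz} (L).
#' @export
stepSize <- function(design, mode = c("eigen", "trace")) {
  mode <- match.arg(mode)
  L <- if (mode == "eigen") {
    2 * (largestGramEigenvalue(design@designA) +
           largestGramEigenvalue(design@designB))
  } else {
    2 * (sum(design@designA^2) + sum(design@designB^2))
  }
  if (L <= 0) stop("all-zero designs: no valid step size")
  list(step = 1 / L, lipschitz = L)
}

#' Solver control parameters
#'
#' @param tol relative-change convergence tolerance on the stacked
#'   coefficient vector (default 1e-6).
#' @param maxIter maximum proximal gradient iterations (default 10000).
#' @param stepMode \code{"eigen"} or \code{"trace"}; see
#'   \code{\link{stepSize}}.
#' @return list of validated control parameters.
#' @export
solverControl <- function(tol = 1e-6, maxIter = 10000L,
                          stepMode = c("eigen", "trace")) {
  stepMode <- match.arg(stepMode)
  if (tol <= 0) stop("tol must be > 0")
  maxIter <- as.integer(maxIter)
  if (maxIter < 1) stop("maxIter must be >= 1")
  list(tol = tol, maxIter = maxIter, stepMode = stepMode)
}

# Core solver in Gram form, shared by solveJoint and the network drivers.
# Ga/Gb are (p-1)x(p-1) Gram matrices, ca/cb the X'y vectors, yty the total
# response sum of squares, L the Lipschitz constant.
solveJointGram <- function(Ga, ca, Gb, cb, yty, L, lam1, lam2, control,
                           init = NULL, trackObjective = TRUE,
                           labels = NULL, warn = TRUE) {
  p <- length(ca)
  if (is.null(init)) init <- list(beta = rep(0, p), betaTilde = rep(0, p))
  res <- cpp_joint_pg(Ga, ca, Gb, cb, yty, lam1, lam2, 1 / L,
                      init$beta, init$betaTilde,
                      control$tol, control$maxIter, trackObjective)
  if (warn && !res$converged)
    warning(sprintf(
      "proximal gradient did not converge in %d iterations", control$maxIter))
  new("JointFit",
      beta = as.numeric(res$beta), betaTilde = as.numeric(res$beta_tilde),
      objective = as.numeric(res$objective), nIter = as.integer(res$n_iter),
      converged = isTRUE(res$converged), step = 1 / L, lipschitz = L,
      lam1 = lam1, lam2 = lam2,
      predictorLabels = if (is.null(labels)) character(p) else labels)
}

#' Solve one gene's joint two-condition sparse regression
#'
#' Minimises the sum of both conditions' residual sums of squares plus
#' \code{lam1} times the l1 norms of both coefficient vectors plus
#' \code{lam2} times the l1 norm of their difference, by proximal gradient
#' iteration with constant step 1/L and the exact per-coordinate prox of
#' \code{\link{proxPair}}.  The problem is convex; the recorded objective
#' path is non-increasing and the iteration reaches the global optimum.
#'
#' @param design a \linkS4class{DesignPair} (centered).
#' @param lam1 nonnegative sparsity penalty.
#' @param lam2 nonnegative fusion penalty on between-condition differences.
#' @param control see \code{\link{solverControl}}.
#' @param init optional warm start: list with \code{beta}, \code{betaTilde}.
#' @return A \linkS4class{JointFit}.  Non-convergence at \code{maxIter}
#'   yields a warning and \code{converged = FALSE}, not an error.
#' @examples
#' sim <- simulateLinearPair(n = 50, pMinus1 = 10, nNonzero = 3,
#'                           nZeroed = 1, nAdded = 1, seed = 1)
#' fit <- solveJoint(sim$design, lam1 = 2, lam2 = 1)
#' fit
#' @export
solveJoint <- function(design, lam1, lam2, control = solverControl(),
                       init = NULL) {
  if (lam1 < 0 || lam2 < 0) stop("penalties must be nonnegative")
  Ga <- crossprod(design@designA)
  Gb <- crossprod(design@designB)
  ca <- as.numeric(crossprod(design@designA, design@responseA))
  cb <- as.numeric(crossprod(design@designB, design@responseB))
  yty <- sum(design@responseA^2) + sum(design@responseB^2)
  L <- stepSize(design, control$stepMode)$lipschitz
  solveJointGram(Ga, ca, Gb, cb, yty, L, lam1, lam2, control, init,
                 labels = design@predictorLabels)
}

#' Coordinate-descent lasso in the no-1/n objective scaling
#'
#' Minimises \eqn{\|y - Zb\|^2 + \lambda s \|b\|_1} (note: sum of squares,
#' no 1/n factor) by cyclic coordinate descent, iterating until the KKT
#' subgradient residual is below 1e-8 (relative to the scale of
#' \eqn{Z'y}).  Used for the stacked common-coefficient problem behind the
#' \code{lambda2Max} bound and for the separate-lasso baseline; also the
#' independent cross-check for the joint solver at \code{lam2 = 0}.
#'
#' @param response numeric response vector (centered).
#' @param design numeric design matrix (centered columns).
#' @param lam nonnegative penalty.
#' @param penaltyScale multiplier \code{s} on the penalty (default 1).
#' @param init optional warm-start coefficient vector.
#' @param maxSweeps maximum coordinate sweeps (default 100000).
#' @return named numeric coefficient vector.
#' @export
lassoCD <- function(response, design, lam, penaltyScale = 1, init = NULL,
                    maxSweeps = 100000L) {
  design <- as.matrix(design)
  if (lam < 0) stop("lam must be >= 0")
  G <- crossprod(design)
  cc <- as.numeric(crossprod(design, response))
  if (is.null(init)) init <- rep(0, ncol(design))
  res <- cpp_lasso_cd(G, cc, lam * penaltyScale, init, 1e-8,
                      as.integer(maxSweeps))
  if (!res$converged)
    warning("coordinate descent did not reach the KKT tolerance")
  setNames(as.numeric(res$b),
           if (is.null(colnames(design))) NULL else colnames(design))
}
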