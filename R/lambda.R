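#' @include solver.R
NULL

#' Smallest penalty that zeroes all coefficients
#'
#' For a single gene's problem this is
#' \eqn{\max\{\max_j 2|x_j'x_i|, \max_j 2|\tilde x_j'\tilde x_i|\}}: at
#' \code{lam1 = lambda1Max} (any \code{lam2}) the joint solution is all
#' zero.  For an \linkS4class{ExpressionPair} the maximum is additionally
#' taken over all target genes, giving the network-level value at which
#' every coefficient of both networks is zero.
#'
#' @param object a \linkS4class{DesignPair} or \linkS4class{ExpressionPair}.
#' @return nonnegative scalar.
#' @export
setGeneric("lambda1Max", function(object) standardGeneric("lambda1Max"))

#' @rdname lambda1Max
#' @export
setMethod("lambda1Max", "DesignPair", function(object) {
  if (ncol(object@designA) == 0) stop("empty design")
  max(2 * abs(crossprod(object@designA, object@responseA)),
      2 * abs(crossprod(object@designB, object@responseB)))
})

#' @rdname lambda1Max
#' @export
setMethod("lambda1Max", "ExpressionPair", function(object) {
  if (ncol(object@exprA) < 2) stop("need at least 2 genes")
  Ga <- crossprod(centerColumns(object@exprA)$matrix)
  Gb <- crossprod(centerColumns(object@exprB)$matrix)
  diag(Ga) <- 0; diag(Gb) <- 0
  max(2 * abs(Ga), 2 * abs(Gb))
})

#' Common coefficient vector shared by both conditions
#'
#' Minimises
#' \eqn{\|x_i - X_{-i}\beta\|^2 + \|\tilde x_i - \tilde X_{-i}\beta\|^2 +
#' 2\lambda_1\|\beta\|_1}, the limit the joint solution fuses to as
#' \code{lam2} grows.  Solved as a lasso on the row-stacked responses and
#' designs with penalty \code{2 * lam1}.
#'
#' @param design a \linkS4class{DesignPair}.
#' @param lam1 nonnegative penalty.
#' @param init optional warm start.
#' @return numeric coefficient vector (length p - 1).
#' @export
commonBetaStar <- function(design, lam1, init = NULL) {
  if (lam1 < 0) stop("lam1 must be >= 0")
  z <- rbind(design@designA, design@designB)
  y <- c(design@responseA, design@responseB)
  lassoCD(y, z, lam1, penaltyScale = 2, init = init)
}

#' Upper bound on the fusion penalty
#'
#' The smallest \code{lam2} at which both conditions' coefficient vectors
#' provably fuse to the common \code{\link{commonBetaStar}} solution is
#' bounded above by
#' \eqn{\max_j \max\{\lambda_1 + |2 x_j' r|, \lambda_1 + |2\tilde x_j'\tilde r|\}}
#' where \eqn{r, \tilde r} are the residuals at the common solution.  The
#' bound is always \code{>= lam1}; solving at \code{(lam1, lambda2Max)}
#' yields elementwise equal coefficient vectors.  For an
#' \linkS4class{ExpressionPair} the maximum is taken over all genes.
#'
#' @param object a \linkS4class{DesignPair} or \linkS4class{ExpressionPair}.
#' @param lam1 nonnegative sparsity penalty the bound is evaluated at.
#' @param betaStar optional precomputed common solution (DesignPair method).
#' @return nonnegative scalar (>= \code{lam1}).
#' @export
setGeneric("lambda2Max",
           function(object, lam1, ...) standardGeneric("lambda2Max"))

#' @rdname lambda2Max
#' @export
setMethod("lambda2Max", "DesignPair", function(object, lam1,
                                               betaStar = NULL) {
  if (lam1 < 0) stop("lam1 must be >= 0")
  if (is.null(betaStar)) betaStar <- commonBetaStar(object, lam1)
  ra <- object@responseA - object@designA %*% betaStar
  rb <- object@responseB - object@designB %*% betaStar
  lam1 + max(2 * abs(crossprod(object@designA, ra)),
             2 * abs(crossprod(object@designB, rb)))
})

#' @rdname lambda2Max
#' @export
setMethod("lambda2Max", "ExpressionPair", function(object, lam1) {
  max(vapply(seq_along(object@geneNames), function(i) {
    lambda2Max(makeDesign(object, i), lam1)
  }, numeric(1)))
})

#' Build a geometric penalty grid
#'
#' \code{lam1} values are \eqn{\lambda_{1\max}\alpha_1^m, m = 0..k_1-1};
#' for each, \code{lam2} values are
#' \eqn{\lambda_{2\max}(\lambda_1)\alpha_2^m, m = 0..k_2-1}.  Grids are
#' stored largest-first so warm-started path solving moves from sparse to
#' dense solutions.  The defaults are the stability-selection grid
#' settings; cross-validation conventionally uses
#' \code{alpha1 = 0.6952, alpha2 = 0.3728, k1 = 20, k2 = 8}.
#'
#' @param object a \linkS4class{DesignPair} or \linkS4class{ExpressionPair}.
#' @param alpha1,alpha2 geometric decay factors in (0, 1).
#' @param k1,k2 grid sizes (>= 1).
#' @return A \linkS4class{LambdaGrid}.
#' @export
setGeneric("buildLambdaGrid",
           function(object, alpha1 = 0.7, alpha2 = 0.8, k1 = 10, k2 = 10)
             standardGeneric("buildLambdaGrid"))

buildGridFrom <- function(l1max, lam2maxFun, alpha1, alpha2, k1, k2) {
  if (alpha1 <= 0 || alpha1 >= 1 || alpha2 <= 0 || alpha2 >= 1)
    stop("decay factors must lie strictly in (0, 1)")
  if (k1 < 1 || k2 < 1) stop("grid sizes must be >= 1")
  lam1 <- l1max * alpha1^(seq_len(k1) - 1)
  lam2 <- lapply(lam1, function(l1) lam2maxFun(l1) * alpha2^(seq_len(k2) - 1))
  new("LambdaGrid", lam1 = lam1, lam2 = lam2,
      alpha1 = alpha1, alpha2 = alpha2)
}

#' @rdname buildLambdaGrid
#' @export
setMethod("buildLambdaGrid", "DesignPair",
  function(object, alpha1 = 0.7, alpha2 = 0.8, k1 = 10, k2 = 10) {
    bs <- NULL # warm start across the lam1 path
    buildGridFrom(lambda1Max(object), function(l1) {
      bs <<- commonBetaStar(object, l1, init = bs)
      lambda2Max(object, l1, betaStar = bs)
    }, alpha1, alpha2, k1, k2)
  })

#' @rdname buildLambdaGrid
#' @export
setMethod("buildLambdaGrid", "ExpressionPair",
  function(object, alpha1 = 0.7, alpha2 = 0.8, k1 = 10, k2 = 10) {
    designs <- lapply(seq_along(object@geneNames),
                      function(i) makeDesign(object, i))
    warm <- vector("list", length(designs))
    buildGridFrom(lambda1Max(object), function(l1) {
      max(vapply(seq_along(designs), function(i) {
        warm[[i]] <<- commonBetaStar(designs[[i]], l1, init = warm[[i]])
        lambda2Max(designs[[i]], l1, betaStar = warm[[i]])
      }, numeric(1)))
    }, alpha1, alpha2, k1, k2)
  })
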