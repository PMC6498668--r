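#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# DesignPair: one gene's regression problem under both conditions
# ---------------------------------------------------------------------------

#' Per-gene regression problem under two conditions
#'
#' Holds the centered response and design for a single target gene in both
#' conditions: response \code{x_i} and design \code{X_-i} (all genes except
#' the target) for condition A, and their condition-B counterparts.  Columns
#' and responses are mean-centered at construction (column means stay below
#' 1e-10 in magnitude), which absorbs the per-gene intercepts of the
#' network regression model.  \code{center = FALSE} is reserved for inputs
#' that are already centered or for deliberately uncentered toy problems.
#'
#' @slot responseA,responseB centered response vectors (one per condition).
#' @slot designA,designB centered design matrices, one column per candidate
#'   regulator; both conditions share column count and labels.
#' @slot predictorLabels character vector of regulator gene identifiers.
#' @slot targetLabel identifier of the target gene.
#' @slot meansA,meansB,responseMeanA,responseMeanB the column/response means
#'   removed at centering, kept for reporting and held-out prediction.
#' @aliases DesignPair
#' @exportClass DesignPair
setClass("DesignPair",
  representation(
    responseA = "numeric", designA = "matrix",
    responseB = "numeric", designB = "matrix",
    predictorLabels = "character", targetLabel = "character",
    meansA = "numeric", meansB = "numeric",
    responseMeanA = "numeric", responseMeanB = "numeric"
  )
)

setValidity("DesignPair", function(object) {
  msgs <- character()
  if (ncol(object@designA) != ncol(object@designB))
    msgs <- c(msgs, "designA and designB must have the same column count")
  if (length(object@predictorLabels) != ncol(object@designA))
    msgs <- c(msgs, "predictorLabels length must match design columns")
  if (length(object@responseA) != nrow(object@designA) ||
      length(object@responseB) != nrow(object@designB))
    msgs <- c(msgs, "response length must match design rows")
  if (!all(is.finite(object@designA)) || !all(is.finite(object@designB)) ||
      !all(is.finite(object@responseA)) || !all(is.finite(object@responseB)))
    msgs <- c(msgs, "non-finite entries in design or response")
  if (object@targetLabel %in% object@predictorLabels)
    msgs <- c(msgs, "the target gene must not appear among predictors")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DesignPair
#'
#' @param responseA,responseB numeric response vectors for the two
#'   conditions (the target gene's expression).
#' @param designA,designB numeric matrices of candidate-regulator
#'   expression (samples x regulators), same columns in both conditions.
#' @param predictorLabels regulator identifiers; defaults to the column
#'   names of \code{designA} or \code{g1..g(p-1)}.
#' @param targetLabel identifier of the target gene.
#' @param center centre columns and responses (default \code{TRUE}); set to
#'   \code{FALSE} only for inputs that are already centered.
#' @return A \linkS4class{DesignPair}.
#' @examples
#' dp <- DesignPair(rnorm(10), matrix(rnorm(30), 10), rnorm(8),
#'                  matrix(rnorm(24), 8))
#' colMeans(designA(dp)) # all ~0
#' @export
DesignPair <- function(responseA, designA, responseB, designB,
                       predictorLabels = NULL, targetLabel = "target",
                       center = TRUE) {
  designA <- as.matrix(designA)
  designB <- as.matrix(designB)
  stopIfNotFinite(designA, "designA"); stopIfNotFinite(designB, "designB")
  stopIfNotFinite(responseA, "responseA"); stopIfNotFinite(responseB, "responseB")
  if (is.null(predictorLabels))
    predictorLabels <- colnames(designA)
  if (is.null(predictorLabels))
    predictorLabels <- paste0("g", seq_len(ncol(designA)))
  mA <- rep(0, ncol(designA)); mB <- rep(0, ncol(designB))
  rmA <- 0; rmB <- 0
  if (center) {
    ca <- centerColumns(designA); cb <- centerColumns(designB)
    designA <- ca$matrix; mA <- ca$means
    designB <- cb$matrix; mB <- cb$means
    rmA <- mean(responseA); responseA <- responseA - rmA
    rmB <- mean(responseB); responseB <- responseB - rmB
  }
  new("DesignPair",
      responseA = as.numeric(responseA), designA = designA,
      responseB = as.numeric(responseB), designB = designB,
      predictorLabels = as.character(predictorLabels),
      targetLabel = targetLabel,
      meansA = mA, meansB = mB, responseMeanA = rmA, responseMeanB = rmB)
}

#' Accessors for DesignPair
#'
#' \code{designA}/\code{designB} return the centered design matrices,
#' \code{responses} the two centered response vectors, and
#' \code{predictorLabels} the regulator identifiers.
#'
#' @param object a \linkS4class{DesignPair}
#' @name DesignPair-accessors
#' @rdname DesignPair-accessors
#' @export
designA <- function(object) object@designA
#' @rdname DesignPair-accessors
#' @export
designB <- function(object) object@designB
#' @rdname DesignPair-accessors
#' @export
responses <- function(object) list(a = object@responseA, b = object@responseB)
#' @rdname DesignPair-accessors
#' @export
predictorLabels <- function(object) object@predictorLabels

setMethod("show", "DesignPair", function(object) {
  cat(sprintf(
    "DesignPair for target '%s': %d predictors; n = %d / %d samples\n",
    object@targetLabel, ncol(object@designA),
    nrow(object@designA), nrow(object@designB)))
})

# ---------------------------------------------------------------------------
# ExpressionPair: full expression matrices under two conditions
# ---------------------------------------------------------------------------

#' Paired expression matrices for two conditions
#'
#' Samples-by-genes expression matrices measured on the same gene set under
#' two conditions.  Gene order is identical across conditions; sample
#' counts may differ.
#'
#' @slot exprA,exprB numeric matrices (samples x genes).
#' @slot geneNames length-p gene identifiers (also the column names).
#' @aliases ExpressionPair
#' @exportClass ExpressionPair
setClass("ExpressionPair",
  representation(exprA = "matrix", exprB = "matrix", geneNames = "character"))

setValidity("ExpressionPair", function(object) {
  msgs <- character()
  if (ncol(object@exprA) != ncol(object@exprB))
    msgs <- c(msgs, "both conditions must have the same gene count")
  if (length(object@geneNames) != ncol(object@exprA))
    msgs <- c(msgs, "geneNames length must equal the gene count")
  if (anyDuplicated(object@geneNames))
    msgs <- c(msgs, "gene names must be unique")
  if (!all(is.finite(object@exprA)) || !all(is.finite(object@exprB)))
    msgs <- c(msgs, "non-finite expression values")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionPair
#'
#' @param exprA,exprB samples-by-genes expression matrices for the two
#'   conditions (same genes, same order).
#' @param geneNames gene identifiers; defaults to \code{colnames(exprA)} or
#'   \code{g1..gp}.
#' @return An \linkS4class{ExpressionPair}.
#' @export
ExpressionPair <- function(exprA, exprB, geneNames = NULL) {
  exprA <- as.matrix(exprA); exprB <- as.matrix(exprB)
  if (is.null(geneNames)) geneNames <- colnames(exprA)
  if (is.null(geneNames)) geneNames <- paste0("g", seq_len(ncol(exprA)))
  colnames(exprA) <- geneNames; colnames(exprB) <- geneNames
  new("ExpressionPair", exprA = exprA, exprB = exprB,
      geneNames = as.character(geneNames))
}

#' Accessors for ExpressionPair
#'
#' @param object an \linkS4class{ExpressionPair}
#' @name ExpressionPair-accessors
#' @rdname ExpressionPair-accessors
#' @export
exprA <- function(object) object@exprA
#' @rdname ExpressionPair-accessors
#' @export
exprB <- function(object) object@exprB
#' @rdname ExpressionPair-accessors
#' @export
geneNames <- function(object) object@geneNames

setMethod("show", "ExpressionPair", function(object) {
  cat(sprintf("ExpressionPair: %d genes; %d + %d samples\n",
              ncol(object@exprA), nrow(object@exprA), nrow(object@exprB)))
})

#' Extract one gene's regression problem from an ExpressionPair
#'
#' Builds the \linkS4class{DesignPair} for gene \code{i}: its expression is
#' the response, all other genes form the design, and everything is
#' centered.
#'
#' @param pair an \linkS4class{ExpressionPair}
#' @param i gene index or name
#' @return A \linkS4class{DesignPair}.
#' @export
makeDesign <- function(pair, i) {
  if (is.character(i)) i <- match(i, pair@geneNames)
  if (is.na(i) || i < 1 || i > ncol(pair@exprA)) stop("unknown gene index")
  DesignPair(pair@exprA[, i], pair@exprA[, -i, drop = FALSE],
             pair@exprB[, i], pair@exprB[, -i, drop = FALSE],
             predictorLabels = pair@geneNames[-i],
             targetLabel = pair@geneNames[i])
}

# ---------------------------------------------------------------------------
# JointFit: solver result for one gene
# ---------------------------------------------------------------------------

#' Solver result for one gene's joint regression
#'
#' @slot beta,betaTilde fitted coefficient vectors for the two conditions
#'   (one column of each network matrix).
#' @slot objective objective values recorded per iteration (non-increasing).
#' @slot nIter iterations used.
#' @slot converged whether the relative-change criterion was met.
#' @slot step,lipschitz the constant step size 1/L and Lipschitz constant L.
#' @slot lam1,lam2 penalties used.
#' @slot predictorLabels regulator identifiers.
#' @aliases JointFit
#' @exportClass JointFit
setClass("JointFit",
  representation(beta = "numeric", betaTilde = "numeric",
                 objective = "numeric", nIter = "integer",
                 converged = "logical", step = "numeric",
                 lipschitz = "numeric", lam1 = "numeric", lam2 = "numeric",
                 predictorLabels = "character"))

setValidity("JointFit", function(object) {
  msgs <- character()
  if (length(object@beta) != length(object@betaTilde))
    msgs <- c(msgs, "beta and betaTilde must have equal length")
  if (!all(is.finite(object@beta)) || !all(is.finite(object@betaTilde)))
    msgs <- c(msgs, "non-finite coefficients")
  if (length(msgs)) msgs else TRUE
})

#' Coefficients of a JointFit
#'
#' @param fit a \linkS4class{JointFit}
#' @return named list with components \code{beta}, \code{betaTilde} and
#'   \code{delta} (= beta - betaTilde).
#' @export
jointCoef <- function(fit) {
  list(beta = setNames(fit@beta, fit@predictorLabels),
       betaTilde = setNames(fit@betaTilde, fit@predictorLabels),
       delta = setNames(fit@beta - fit@betaTilde, fit@predictorLabels))
}

#' @describeIn jointCoef recorded objective path
#' @export
objectivePath <- function(fit) fit@objective

setMethod("show", "JointFit", function(object) {
  cat(sprintf(
    "JointFit: lambda1 = %.4g, lambda2 = %.4g; %d/%d nonzero; %d iter (%s)\n",
    object@lam1, object@lam2, sum(object@beta != 0),
    sum(object@betaTilde != 0), object@nIter,
    if (object@converged) "converged" else "NOT converged"))
})

# ---------------------------------------------------------------------------
# NetworkPair
# ---------------------------------------------------------------------------

#' A pair of inferred (or true) network coefficient matrices
#'
#' Entry \code{[j, i]} is the coefficient of gene j in gene i's regression,
#' i.e. the directed edge j -> i ("source regulates target"); column i
#' holds gene i's coefficient vector.  Diagonals are structurally zero.
#'
#' @slot b,bTilde p x p coefficient matrices for conditions A and B.
#' @slot geneNames gene identifiers (row and column names).
#' @slot fitInfo free-form list (e.g. per-gene convergence flags).
#' @aliases NetworkPair
#' @exportClass NetworkPair
setClass("NetworkPair",
  representation(b = "matrix", bTilde = "matrix", geneNames = "character",
                 fitInfo = "list"))

setValidity("NetworkPair", function(object) {
  msgs <- character()
  if (!all(dim(object@b) == dim(object@bTilde)) ||
      nrow(object@b) != ncol(object@b))
    msgs <- c(msgs, "b and bTilde must be square matrices of equal size")
  if (length(object@geneNames) != nrow(object@b))
    msgs <- c(msgs, "geneNames length must equal matrix dimension")
  if (nrow(object@b) > 0 &&
      (any(diag(object@b) != 0) || any(diag(object@bTilde) != 0)))
    msgs <- c(msgs, "diagonals must be zero (no self-loops)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a NetworkPair
#'
#' @param b,bTilde square coefficient matrices (entry [j, i] = edge j -> i)
#'   with zero diagonals.
#' @param geneNames gene identifiers.
#' @param fitInfo optional list of fitting metadata.
#' @return A \linkS4class{NetworkPair}.
#' @export
NetworkPair <- function(b, bTilde, geneNames = NULL, fitInfo = list()) {
  b <- as.matrix(b); bTilde <- as.matrix(bTilde)
  if (is.null(geneNames)) geneNames <- colnames(b)
  if (is.null(geneNames)) geneNames <- paste0("g", seq_len(ncol(b)))
  dimnames(b) <- dimnames(bTilde) <- list(geneNames, geneNames)
  new("NetworkPair", b = b, bTilde = bTilde,
      geneNames = as.character(geneNames), fitInfo = fitInfo)
}

#' Accessors for NetworkPair
#'
#' \code{coefA}/\code{coefB} return the condition-specific coefficient
#' matrices, \code{networkDelta} their difference B - B~, and
#' \code{fitInfo} the fitting metadata list.
#'
#' @param object a \linkS4class{NetworkPair}
#' @name NetworkPair-accessors
#' @rdname NetworkPair-accessors
#' @export
coefA <- function(object) object@b
#' @rdname NetworkPair-accessors
#' @export
coefB <- function(object) object@bTilde
#' @rdname NetworkPair-accessors
#' @export
networkDelta <- function(object) object@b - object@bTilde
#' @rdname NetworkPair-accessors
#' @export
fitInfo <- function(object) object@fitInfo

setMethod("show", "NetworkPair", function(object) {
  d <- networkDelta(object)
  diag(d) <- 0
  cat(sprintf(
    "NetworkPair: %d genes; %d / %d edges; %d differing entries\n",
    nrow(object@b), sum(object@b != 0), sum(object@bTilde != 0),
    sum(d != 0)))
})

# ---------------------------------------------------------------------------
# LambdaGrid
# ---------------------------------------------------------------------------

#' Geometric penalty grid
#'
#' \code{lam1} starts at \code{lambda1Max} and decays by \code{alpha1};
#' for each lam1, the lam2 sequence starts at the \code{lambda2Max} bound
#' for that lam1 and decays by \code{alpha2}.
#'
#' @slot lam1 decreasing lambda1 values (length k1).
#' @slot lam2 list of length k1; decreasing lambda2 values (length k2) for
#'   each lam1.
#' @slot alpha1,alpha2 geometric decay factors in (0, 1).
#' @aliases LambdaGrid
#' @exportClass LambdaGrid
setClass("LambdaGrid",
  representation(lam1 = "numeric", lam2 = "list",
                 alpha1 = "numeric", alpha2 = "numeric"))

setValidity("LambdaGrid", function(object) {
  msgs <- character()
  if (length(object@lam2) != length(object@lam1))
    msgs <- c(msgs, "lam2 list length must equal lam1 length")
  if (length(object@lam1) > 1 && any(diff(object@lam1) > 0))
    msgs <- c(msgs, "lam1 values must be decreasing")
  if (length(msgs)) msgs else TRUE
})

#' Enumerate all (lambda1, lambda2) pairs of a grid
#'
#' @param grid a \linkS4class{LambdaGrid}
#' @return A k1*k2 x 2 matrix with columns \code{lam1}, \code{lam2}, in
#'   lambda1-major order (largest first), suitable for warm-started path
#'   solving.
#' @export
lambdaPairs <- function(grid) {
  out <- do.call(rbind, lapply(seq_along(grid@lam1), function(i) {
    cbind(lam1 = grid@lam1[i], lam2 = grid@lam2[[i]])
  }))
  rownames(out) <- NULL
  out
}

setMethod("show", "LambdaGrid", function(object) {
  cat(sprintf(
    "LambdaGrid: k1 = %d (alpha1 = %.4g, max %.4g), k2 = %d (alpha2 = %.4g); %d pairs\n",
    length(object@lam1), object@alpha1,
    if (length(object@lam1)) object@lam1[1] else NA_real_,
    if (length(object@lam2)) length(object@lam2[[1]]) else 0L,
    object@alpha2, length(object@lam1) * length(object@lam2[[1]])))
})

# ---------------------------------------------------------------------------
# CVResult
# ---------------------------------------------------------------------------

#' Cross-validation result over a penalty grid
#'
#' @slot pe k1 x k2 matrix of mean held-out prediction error.
#' @slot se matching matrix of standard errors across folds.
#' @slot lam1Min,lam2Min penalties minimising prediction error.
#' @slot lam1Opt,lam2Opt two-standard-error selections (>= the minimisers).
#' @slot grid the \linkS4class{LambdaGrid} evaluated.
#' @aliases CVResult
#' @exportClass CVResult
setClass("CVResult",
  representation(pe = "matrix", se = "matrix",
                 lam1Min = "numeric", lam2Min = "numeric",
                 lam1Opt = "numeric", lam2Opt = "numeric",
                 grid = "LambdaGrid"))

setValidity("CVResult", function(object) {
  msgs <- character()
  if (any(object@pe < 0)) msgs <- c(msgs, "prediction errors must be >= 0")
  if (object@lam1Opt < object@lam1Min - 1e-12)
    msgs <- c(msgs, "lam1Opt must be >= lam1Min")
  if (object@lam2Opt < object@lam2Min - 1e-12)
    msgs <- c(msgs, "lam2Opt must be >= lam2Min")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: PE min %.4g at (%.4g, %.4g); two-SE choice (%.4g, %.4g)\n",
    min(object@pe), object@lam1Min, object@lam2Min,
    object@lam1Opt, object@lam2Opt))
})

# ---------------------------------------------------------------------------
# StabilityFrequencies
# ---------------------------------------------------------------------------

#' Edge selection frequencies from stability selection
#'
#' Frequencies are proportions in [0, 1]: counts of nonzero estimates over
#' the 2NK half-sample refits (N subsample rounds, two halves each, K
#' penalty pairs), divided by 2NK.  Entry [j, i] refers to edge j -> i.
#'
#' @slot r,rTilde p x p selection frequencies per condition.
#' @slot deltaR p x p changed-edge frequencies.
#' @slot nRuns number of subsample rounds N.
#' @slot nPairs number of penalty pairs K.
#' @aliases StabilityFrequencies
#' @exportClass StabilityFrequencies
setClass("StabilityFrequencies",
  representation(r = "matrix", rTilde = "matrix", deltaR = "matrix",
                 nRuns = "integer", nPairs = "integer"))

setValidity("StabilityFrequencies", function(object) {
  msgs <- character()
  rng <- range(object@r, object@rTilde, object@deltaR)
  if (rng[1] < 0 || rng[2] > 1)
    msgs <- c(msgs, "frequencies must lie in [0, 1]")
  if (nrow(object@r) > 0 &&
      (any(diag(object@r) != 0) || any(diag(object@rTilde) != 0) ||
       any(diag(object@deltaR) != 0)))
    msgs <- c(msgs, "diagonal frequencies must be zero")
  if (length(msgs)) msgs else TRUE
})

#' Accessors for StabilityFrequencies
#'
#' @param object a \linkS4class{StabilityFrequencies}
#' @name StabilityFrequencies-accessors
#' @rdname StabilityFrequencies-accessors
#' @export
edgeFreqA <- function(object) object@r
#' @rdname StabilityFrequencies-accessors
#' @export
edgeFreqB <- function(object) object@rTilde
#' @rdname StabilityFrequencies-accessors
#' @export
changedFreq <- function(object) object@deltaR

setMethod("show", "StabilityFrequencies", function(object) {
  cat(sprintf(
    "StabilityFrequencies: %d genes; N = %d runs x K = %d pairs; max delta-r = %.3g\n",
    nrow(object@r), object@nRuns, object@nPairs, max(object@deltaR)))
})

# ---------------------------------------------------------------------------
# PRResult / DetectionStats
# ---------------------------------------------------------------------------

#' Precision-recall curve and AUPR for a ranked edge list
#'
#' @slot precision,recall curve coordinates (one point per tie group).
#' @slot aupr average precision in [0, 1].
#' @slot nTrue number of true positives available.
#' @slot nCandidates length of the ranked candidate list.
#' @aliases PRResult
#' @exportClass PRResult
setClass("PRResult",
  representation(precision = "numeric", recall = "numeric", aupr = "numeric",
                 nTrue = "integer", nCandidates = "integer"))

setValidity("PRResult", function(object) {
  msgs <- character()
  if (object@aupr < 0 || object@aupr > 1)
    msgs <- c(msgs, "aupr must be in [0, 1]")
  if (length(object@recall) > 1 && any(diff(object@recall) < -1e-12))
    msgs <- c(msgs, "recall must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' Accessors for PRResult
#'
#' \code{aupr} returns the area under the precision-recall curve,
#' \code{prCurve} the curve itself as a data.frame.
#'
#' @param object a \linkS4class{PRResult}
#' @name PRResult-accessors
#' @rdname PRResult-accessors
#' @export
aupr <- function(object) object@aupr
#' @rdname PRResult-accessors
#' @export
prCurve <- function(object)
  data.frame(recall = object@recall, precision = object@precision)

setMethod("show", "PRResult", function(object) {
  cat(sprintf("PRResult: AUPR = %.4f (%d true, %d candidates)\n",
              object@aupr, object@nTrue, object@nCandidates))
})

#' Detection power and false discovery rate
#'
#' @slot power tp / (tp + fn); \code{NaN} when no true positives exist.
#' @slot fdr fp / max(1, tp + fp) (so an empty detection has fdr 0).
#' @slot tp,fp,fn counts.
#' @aliases DetectionStats
#' @exportClass DetectionStats
setClass("DetectionStats",
  representation(power = "numeric", fdr = "numeric",
                 tp = "integer", fp = "integer", fn = "integer"))

setMethod("show", "DetectionStats", function(object) {
  cat(sprintf("DetectionStats: power = %.3f, FDR = %.3f (tp %d, fp %d, fn %d)\n",
              object@power, object@fdr, object@tp, object@fp, object@fn))
})
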