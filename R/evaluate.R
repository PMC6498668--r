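#' @include AllClasses.R
NULL

# Flatten a matrix to its off-diagonal entries; vectors pass through.
offDiagonal <- function(x) {
  if (is.matrix(x)) x[row(x) != col(x)] else x
}

#' Detection power and false discovery rate
#'
#' Compares an estimated nonzero mask with the truth.  Matrices are
#' compared over off-diagonal entries only.  An empty detection has power 0
#' and FDR 0 (the denominator of the FDR is floored at 1).
#'
#' @param estimated,truth logical (or coercible) vectors or matrices of the
#'   same shape.
#' @return A \linkS4class{DetectionStats}.
#' @export
detectionStats <- function(estimated, truth) {
  if (!all(dim(as.matrix(estimated)) == dim(as.matrix(truth))))
    stop("estimated and truth shapes differ")
  est <- as.logical(offDiagonal(estimated))
  tru <- as.logical(offDiagonal(truth))
  tp <- sum(est & tru); fp <- sum(est & !tru); fn <- sum(!est & tru)
  new("DetectionStats",
      power = if (tp + fn > 0) tp / (tp + fn) else NaN,
      fdr = fp / max(1, tp + fp),
      tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Pooled precision-recall curve and AUPR of ranked candidates
#'
#' Candidates (entries with a strictly positive score) from all replicates
#' are pooled into one list ranked by descending score; tied scores are
#' processed as a block.  Precision and recall are computed cumulatively
#' and the AUPR is the average precision: the sum over tie blocks of the
#' block-end precision times the recall increment.  The recall denominator
#' counts every true positive, including those that never enter the
#' candidate list, so a ranking that misses true edges cannot reach
#' recall 1.
#'
#' @param scores numeric vector/matrix of ranking scores (e.g. changed-edge
#'   stability frequencies), or a list of them (one per replicate).
#'   Matrix diagonals are ignored.
#' @param truth logical vector/matrix (or list) of true positives, matching
#'   \code{scores} element-wise.
#' @return A \linkS4class{PRResult}.  Errors when no true positives exist
#'   anywhere (recall undefined).
#' @examples
#' pooledPR(c(3, 2, 1), c(TRUE, FALSE, TRUE))  # AP = 0.8333
#' @export
pooledPR <- function(scores, truth) {
  if (!is.list(scores)) scores <- list(scores)
  if (!is.list(truth)) truth <- list(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have the same number of replicates")
  s <- unlist(lapply(scores, offDiagonal), use.names = FALSE)
  tr <- as.logical(unlist(lapply(truth, offDiagonal), use.names = FALSE))
  if (length(s) != length(tr)) stop("scores and truth shapes differ")
  nTrue <- sum(tr)
  if (nTrue == 0) stop("no true positives: recall is undefined")
  cand <- s > 0
  s <- s[cand]; tr <- tr[cand]
  if (!length(s))
    return(new("PRResult", precision = numeric(0), recall = numeric(0),
               aupr = 0, nTrue = as.integer(nTrue), nCandidates = 0L))
  ord <- order(-s)
  s <- s[ord]; tr <- tr[ord]
  # block boundaries: last index of each tie group
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  cumTP <- cumsum(tr)[ends]
  prec <- cumTP / ends
  rec <- cumTP / nTrue
  ap <- sum(prec * diff(c(0, rec)))
  new("PRResult", precision = prec, recall = rec, aupr = ap,
      nTrue = as.integer(nTrue), nCandidates = length(s))
}
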