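#' @include AllClasses.R
NULL

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with one header row of gene names and a
#' first column of sample identifiers (samples x genes, the default
#' orientation).  Set \code{genesInRows = TRUE} for the transposed layout
#' (genes x samples); the returned matrix is always samples x genes.
#'
#' @param path file path.
#' @param genesInRows transpose a genes-by-samples file (default FALSE).
#' @return numeric matrix with row (sample) and column (gene) labels.
#' @export
readExpressionMatrix <- function(path, genesInRows = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (row '%s', column '%s')",
                                  rownames(m)[bad[1, 1]],
                                  colnames(m)[bad[1, 2]]) else ""
    stop("non-numeric cell in ", path, loc)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop(sprintf("non-finite value in %s at row '%s', column '%s'",
                 path, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  if (genesInRows) m <- t(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Samples x genes with a header row of gene names and a first column of
#' sample identifiers; round-trips through
#' \code{\link{readExpressionMatrix}}.
#'
#' @param m numeric matrix (samples x genes).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair of expression matrices into an ExpressionPair
#'
#' @param pathA,pathB TSV files for the two conditions (same genes).
#' @param genesInRows see \code{\link{readExpressionMatrix}}.
#' @return An \linkS4class{ExpressionPair}.
#' @export
readExpressionPair <- function(pathA, pathB, genesInRows = FALSE) {
  a <- readExpressionMatrix(pathA, genesInRows)
  b <- readExpressionMatrix(pathB, genesInRows)
  if (!identical(colnames(a), colnames(b)))
    stop("gene sets of the two files differ")
  ExpressionPair(a, b)
}

#' Write a labeled square matrix (adjacency or coefficients) as TSV
#'
#' @param m square matrix with gene dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <-
      if (!is.null(colnames(m))) colnames(m) else paste0("g", seq_len(nrow(m)))
  }
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked changed-edge table as TSV
#'
#' Columns: \code{source_gene}, \code{target_gene}, \code{b},
#' \code{b_tilde}, \code{delta_b}, \code{delta_r}.  The direction
#' convention is source regulates target (entry [source, target] of the
#' coefficient matrices).  Ordering is preserved from
#' \code{\link{rankChangedEdges}}; an empty table yields a header-only
#' file.
#'
#' @param edges data.frame from \code{\link{rankChangedEdges}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeTable <- function(edges, path) {
  out <- data.frame(source_gene = edges$source, target_gene = edges$target,
                    b = edges$b, b_tilde = edges$bTilde,
                    delta_b = edges$deltaB, delta_r = edges$deltaR)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an edge table written by \code{\link{writeEdgeTable}}
#'
#' @param path file path.
#' @return data.frame with the columns of \code{\link{rankChangedEdges}}.
#' @export
readEdgeTable <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c("character", "character", rep("numeric", 4)))
  data.frame(source = df$source_gene, target = df$target_gene,
             b = df$b, bTilde = df$b_tilde, deltaB = df$delta_b,
             deltaR = df$delta_r, stringsAsFactors = FALSE)
}
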