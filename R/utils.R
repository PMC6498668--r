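# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; if `seed`
# is NULL the current RNG stream is used (and advanced).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derivation, kept well below 2^31.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(k) * 9973L) %% 2147483587L
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite entries", what))
  invisible(x)
}

# Largest eigenvalue of Z'Z, computed on the smaller of the two Gram forms
# (Z'Z and ZZ' share nonzero spectrum).
largestGramEigenvalue <- function(z) {
  g <- if (nrow(z) <= ncol(z)) tcrossprod(z) else crossprod(z)
  max(0, eigen(g, symmetric = TRUE, only.values = TRUE)$values[1L])
}

# Linear-interpolation percentile (R's default type 7), q in [0, 100].
pctile <- function(x, q) as.numeric(quantile(x, q / 100, type = 7, names = FALSE))
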