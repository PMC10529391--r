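# Internal numerical helpers shared across the identification pipeline.

# Moore-Penrose pseudo-inverse via economy SVD with a relative singular-value
# cutoff (default 1e-12 of the largest). No explicit matrix inversion is used
# anywhere in the subspace pipeline.
pinv_svd <- function(x, rtol = 1e-12) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("pinv_svd: non-finite entries")
  s <- svd(x)
  if (length(s$d) == 0L || s$d[1] == 0) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  keep <- s$d > rtol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# CLI log lines (no cryptographic intent).
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # stay in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
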