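#' Block Hankel matrices of a PA signal
#'
#' Arranges a sampled output into the past/future block Hankel partition used
#' by subspace identification. Entry `(r, c)` of the stacked matrix
#' `rbind(Yp, Yf)` is sample `y[r + c - 1]` (1-based), so `Yp` holds block rows
#' `0..i-1` and `Yf` rows `i..2i-1`. The shifted partition moves the first row
#' of `Yf` to the bottom of `Yp`, giving `Yp_plus` (`i+1` rows) and `Yf_minus`
#' (`i-1` rows), used to form the time-shifted state estimate.
#'
#' @param signal a [pa_signal()] or numeric vector.
#' @param i number of block rows (per partition); must be `>= 2`.
#' @param j number of columns, or `NULL` (default) to use all samples:
#'   `j = length(signal) - 2 * i + 1`.
#' @return An object of class `hankel_data` with fields `Yp`, `Yf`, `Yp_plus`,
#'   `Yf_minus`, `i`, `j`.
#' @examples
#' h <- build_hankel(0:5, i = 2)
#' h$Yp # rows (0,1,2) and (1,2,3)
#' @export
build_hankel <- function(signal, i, j = NULL) {
  y <- if (inherits(signal, "pa_signal")) signal$samples else as.numeric(signal)
  i <- as.integer(i)
  if (i < 2L) stop("build_hankel: 'i' must be >= 2")
  n <- length(y)
  if (is.null(j)) j <- n - 2L * i + 1L
  j <- as.integer(j)
  need <- 2L * i + j - 1L
  if (j < 1L || need > n) {
    stop(sprintf(
      "build_hankel: signal too short, need at least %d samples for i = %d, j = %d (have %d)",
      max(need, 2L * i), i, max(j, 1L), n))
  }
  row_of <- function(r) y[(r + 1L):(r + j)] # r is the 0-based lag
  H <- t(vapply(0:(2L * i - 1L), row_of, numeric(j)))
  structure(list(
    Yp = H[1:i, , drop = FALSE],
    Yf = H[(i + 1L):(2L * i), , drop = FALSE],
    Yp_plus = H[1:(i + 1L), , drop = FALSE],
    Yf_minus = H[(i + 2L):(2L * i), , drop = FALSE],
    i = i, j = j
  ), class = "hankel_data")
}

#' @export
print.hankel_data <- function(x, ...) {
  cat(sprintf("Block Hankel data: i = %d block rows, j = %d columns\n", x$i, x$j))
  invisible(x)
}

#' Orthogonal (or oblique) row-space projection
#'
#' Projects the rows of `Yf` onto the row space of `Wp`:
#' \deqn{O_i = Y_f W_p^\top (W_p W_p^\top)^{+} W_p,}
#' the least-squares reconstruction of `Yf` from linear combinations of `Wp`'s
#' rows. When a future-input block `Uf` is supplied, the oblique projection of
#' `Yf` onto `Wp` along the row space of `Uf` is returned (both matrices are
#' first projected onto the orthogonal complement of `Uf`'s row space). All
#' inverses are SVD pseudo-inverses with relative cutoff 1e-12.
#'
#' @param Yf matrix of future outputs (rows x columns).
#' @param Wp matrix of past data (instruments); same column count as `Yf`.
#' @param Uf optional matrix of future inputs; same column count.
#' @return Matrix of the same shape as `Yf`.
#' @export
orthogonal_project <- function(Yf, Wp, Uf = NULL) {
  Yf <- as.matrix(Yf); Wp <- as.matrix(Wp)
  if (ncol(Yf) != ncol(Wp)) {
    stop("orthogonal_project: 'Yf' and 'Wp' must have the same column count")
  }
  if (!is.null(Uf)) {
    Uf <- as.matrix(Uf)
    if (ncol(Uf) != ncol(Yf)) {
      stop("orthogonal_project: 'Uf' must have the same column count")
    }
    # project out the row space of Uf, then project orthogonally
    P_perp <- diag(ncol(Uf)) - t(Uf) %*% pinv_svd(Uf %*% t(Uf)) %*% Uf
    Yf <- Yf %*% P_perp
    Wp <- Wp %*% P_perp
  }
  G <- Yf %*% t(Wp) %*% pinv_svd(Wp %*% t(Wp))
  G %*% Wp
}

#' Model-order selection from singular values
#'
#' Given the non-increasing singular values of the projected Hankel data,
#' returns the number of leading values before the largest relative gap
#' `s_k / s_{k+1}`, restricted to values with `s_k / s_1 >= threshold_ratio`.
#' On clean second-order data the third singular value collapses and the rule
#' returns 2.
#'
#' @param singular_values non-increasing, non-negative numeric vector.
#' @param threshold_ratio smallest relative magnitude (to `s_1`) a singular
#'   value may have and still be counted as signal; default `1e-2`.
#' @return Integer order; 0 (with a warning) for an all-zero sequence.
#' @examples
#' estimate_order(c(10, 9, 0.01, 0.005)) # 2
#' @export
estimate_order <- function(singular_values, threshold_ratio = 1e-2) {
  s <- as.numeric(singular_values)
  if (length(s) == 0L) stop("estimate_order: empty sequence")
  if (any(s < 0) || (length(s) > 1L && any(diff(s) > 1e-9 * max(s)))) {
    stop("estimate_order: singular values must be non-increasing and >= 0")
  }
  if (s[1] == 0) {
    warning("estimate_order: all singular values are zero; returning order 0")
    return(0L)
  }
  eligible <- which(s / s[1] >= threshold_ratio)
  K <- max(eligible)
  if (K >= length(s)) return(as.integer(K))
  gaps <- s[1:K] / s[2:(K + 1L)] # Inf when the next value is exactly 0
  as.integer(which.max(gaps))
}
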