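#' Discrete-time state-space model
#'
#' Container for a single-output discrete-time state-space model
#' \eqn{x_{k+1} = A x_k + B u_k}, \eqn{y_k = C x_k}, with sampling interval
#' `ts`. Throughout the package the impulse response of a model is the free
#' response from the state `B`: \eqn{y_k = C A^k B}, i.e. `B` is the state
#' immediately after a unit impulse, so `y_0 = C B`.
#'
#' @param A n x n system matrix.
#' @param B n x 1 input (or impulse-equivalent initial-state) matrix.
#' @param C 1 x n output matrix.
#' @param ts sampling interval in seconds.
#' @return An object of class `state_space_model` with fields `A`, `B`, `C`,
#'   `n` (order) and `ts`.
#' @export
state_space_model <- function(A, B, C, ts) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (ncol(A) != n) stop("state_space_model: 'A' must be square")
  if (!all(dim(B) == c(n, 1L))) stop("state_space_model: 'B' must be n x 1")
  if (!all(dim(C) == c(1L, n))) stop("state_space_model: 'C' must be 1 x n")
  if (!is.finite(ts) || ts <= 0) stop("state_space_model: 'ts' must be positive")
  structure(list(A = A, B = B, C = C, n = n, ts = ts),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  cat(sprintf("Discrete state-space model: order %d, ts = %.4g s\n", x$n, x$ts))
  cat("  |eig(A)| =", paste(sprintf("%.6g", Mod(ev)), collapse = ", "),
      if (all(Mod(ev) < 1)) "(stable)\n" else "(UNSTABLE)\n")
  invisible(x)
}

#' Sampled impulse response of a state-space model
#'
#' Computes \eqn{y_k = C A^k B} for `k = 0, ..., n_samples - 1` by state
#' propagation (no matrix powers are formed).
#'
#' @param model a [state_space_model()].
#' @param n_samples number of output samples.
#' @return Numeric vector of length `n_samples`.
#' @export
impulse_response <- function(model, n_samples) {
  stopifnot(inherits(model, "state_space_model"))
  n_samples <- as.integer(n_samples)
  y <- numeric(n_samples)
  x <- model$B
  for (k in seq_len(n_samples)) {
    y[k] <- drop(model$C %*% x)
    x <- model$A %*% x
  }
  y
}

#' @rdname state_space_model
#' @param model a `state_space_model`.
#' @export
is_stable <- function(model) {
  stopifnot(inherits(model, "state_space_model"))
  all(Mod(eigen(model$A, only.values = TRUE)$values) < 1)
}
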