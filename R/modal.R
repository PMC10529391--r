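#' Modal parameters from an identified system matrix
#'
#' Maps a discrete-time eigenvalue \eqn{\lambda} of the system matrix to the
#' continuous-time natural frequency and damping ratio through the principal
#' branch of the complex logarithm:
#' \deqn{\omega_n = |\ln\lambda| / t_s, \qquad
#'       \zeta = -\cos(\angle \ln\lambda).}
#' Among the eigenvalues of `A` the complex eigenvalue with positive imaginary
#' part and largest modulus is preferred (conjugate pairs carry identical
#' modal parameters); if all eigenvalues are real, the largest-modulus real
#' pole is used, for which \eqn{0 < \lambda < 1} gives \eqn{\zeta = 1}.
#'
#' @param A system matrix (or a [state_space_model()]).
#' @param ts sampling interval in seconds; ignored (taken from the model) when
#'   `A` is a `state_space_model`.
#' @return A [second_order_params()] with `gain = NA` (not identifiable from
#'   `A` alone).
#' @examples
#' m <- discretize(second_order_params(1e7, 0.2), ts = 1e-8)
#' extract_modal_params(m$A, 1e-8) # recovers omega_n = 1e7, zeta = 0.2
#' @export
extract_modal_params <- function(A, ts) {
  if (inherits(A, "state_space_model")) {
    ts <- A$ts
    A <- A$A
  }
  if (!is.finite(ts) || ts <= 0) stop("extract_modal_params: 'ts' must be positive")
  ev <- eigen(as.matrix(A), only.values = TRUE)$values
  cplx <- ev[Im(ev) > 0]
  lambda <- if (length(cplx)) {
    cplx[which.max(Mod(cplx))]
  } else {
    ev_real <- Re(ev[abs(Im(ev)) <= .Machine$double.eps * Mod(ev)])
    if (!length(ev_real)) ev_real <- Re(ev)
    ev_real[which.max(abs(ev_real))]
  }
  if (Mod(lambda) == 0) stop("extract_modal_params: singular pole (lambda = 0)")
  if (Im(lambda) == 0 && Re(lambda) < 0) {
    warning("extract_modal_params: eigenvalue on the negative real axis; ",
            "principal-branch log is ambiguous at the Nyquist frequency")
  }
  ln_lambda <- log(as.complex(lambda)) # principal branch
  omega_n <- Mod(ln_lambda) / ts
  zeta <- -cos(Arg(ln_lambda))
  # exactly undamped poles give zeta = -cos(pi/2) = -6e-17; clamp the noise
  if (zeta < 0 && zeta > -1e-12) zeta <- 0
  second_order_params(omega_n = omega_n, zeta = zeta, gain = NA_real_)
}

#' Normalized root-mean-square error of a model fit
#'
#' Fit percentage between a measured trace and a model output:
#' \deqn{\mathrm{NRMSE} = \Big(1 - \frac{\lVert y_{PA} - y\rVert_2}
#'       {\lVert y_{PA} - \bar y_{PA}\rVert_2}\Big) \cdot 100.}
#' 100 is a perfect reproduction, 0 matches the mean predictor, and negative
#' values indicate a fit worse than the mean.
#'
#' @param y_measured measured sequence (length `>= 2`, not constant).
#' @param y_model model sequence of the same length.
#' @return Fit quality in percent (`<= 100`).
#' @examples
#' nrmse(c(1, 2, 3), c(1, 2, 4)) # (1 - 1/sqrt(2)) * 100
#' @export
nrmse <- function(y_measured, y_model) {
  y_measured <- as.numeric(y_measured)
  y_model <- as.numeric(y_model)
  if (length(y_measured) != length(y_model)) stop("nrmse: lengths differ")
  if (length(y_measured) < 2L) stop("nrmse: need at least 2 samples")
  denom <- sqrt(sum((y_measured - mean(y_measured))^2))
  if (denom == 0) stop("nrmse: undefined denominator, 'y_measured' is constant")
  (1 - sqrt(sum((y_measured - y_model)^2)) / denom) * 100
}

#' Physical ratios of the second-order PA model
#'
#' The identified modal parameters map to the lumped stiffness-to-mass and
#' damping-to-mass ratios of the mechanical analogue: \eqn{k/m = \omega_n^2}
#' and \eqn{b/m = 2\zeta\omega_n}.
#'
#' @param params a [second_order_params()].
#' @return Named list with `k_over_m` (s^-2) and `b_over_m` (s^-1).
#' @export
physical_ratios <- function(params) {
  stopifnot(inherits(params, "second_order_params"))
  list(k_over_m = params$omega_n^2,
       b_over_m = 2 * params$zeta * params$omega_n)
}

#' Polynomial trend of a modal parameter against PVA concentration
#'
#' Ordinary least-squares polynomial fit of a parameter (damping ratio,
#' natural frequency, ...) against PVA concentration, with the coefficient of
#' determination. Across the hydrogel panel the damping ratio rises linearly
#' and the natural frequency falls along a quadratic with concentration.
#'
#' @param concentrations PVA concentrations in percent.
#' @param values parameter values, same length.
#' @param degree polynomial degree, 1 (linear) or 2 (quadratic).
#' @return An object of class `trend_fit` with fields `degree`, `coefficients`
#'   (ascending powers: intercept first), `r_squared`, `x`, `y` and `fitted`.
#' @export
fit_concentration_trend <- function(concentrations, values, degree = 1) {
  x <- as.numeric(concentrations)
  y <- as.numeric(values)
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("fit_concentration_trend: 'degree' must be 1 or 2")
  if (length(x) != length(y)) stop("fit_concentration_trend: lengths differ")
  if (length(x) < degree + 2L) {
    stop(sprintf("fit_concentration_trend: under-determined, need >= %d points for degree %d",
                 degree + 2L, degree))
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(
    degree = degree,
    coefficients = unname(stats::coef(fit)),
    r_squared = r_squared,
    x = x, y = y,
    fitted = unname(stats::fitted(fit))
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Degree-%d trend fit: R^2 = %.4f\n  coefficients (ascending powers): %s\n",
              x$degree, x$r_squared,
              paste(sprintf("%.6g", x$coefficients), collapse = ", ")))
  invisible(x)
}
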