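#' Second-order oscillator parameters
#'
#' The photoacoustic pressure trace of a hydrogel phantom is modeled as the
#' impulse response of a second-order linear time-invariant mechanical system
#' parameterized by its natural frequency \eqn{\omega_n} (rad/s), damping
#' ratio \eqn{\zeta} (dimensionless) and an impulse gain that lumps the
#' thermoelastic forcing magnitude (Gruneisen efficiency, absorbed fluence and
#' heating-rate shape are not separately identifiable from one output trace).
#'
#' @param omega_n natural frequency in rad/s; must be positive.
#' @param zeta damping ratio, `>= 0`. Values below 1 are underdamped, the
#'   regime assumed for PA ring-downs.
#' @param gain impulse magnitude in volt-seconds; scales the response.
#' @return An object of class `second_order_params`.
#' @seealso [simulate_pa_signal()], [discretize()], [physical_ratios()]
#' @examples
#' p <- second_order_params(omega_n = 2 * pi * 2.25e6, zeta = 0.3)
#' is_underdamped(p)
#' @export
second_order_params <- function(omega_n, zeta, gain = 1) {
  if (!is.finite(omega_n) || omega_n <= 0) {
    stop("second_order_params: 'omega_n' must be positive (rad/s)")
  }
  if (!is.finite(zeta) || zeta < 0) {
    stop("second_order_params: 'zeta' must be >= 0")
  }
  structure(list(omega_n = omega_n, zeta = zeta, gain = gain),
            class = "second_order_params")
}

#' @rdname second_order_params
#' @param params a `second_order_params` object.
#' @export
is_underdamped <- function(params) {
  stopifnot(inherits(params, "second_order_params"))
  params$zeta >= 0 && params$zeta < 1
}

#' @export
print.second_order_params <- function(x, ...) {
  cat(sprintf(
    "Second-order params: omega_n = %.6g rad/s (f_n = %.4g MHz), zeta = %.4g%s, gain = %.4g\n",
    x$omega_n, x$omega_n / (2 * pi * 1e6), x$zeta,
    if (x$zeta < 1) " (underdamped)" else "", x$gain))
  invisible(x)
}

#' Simulate a photoacoustic signal as a second-order impulse response
#'
#' Generates the closed-form impulse response of an underdamped second-order
#' system,
#' \deqn{y(t) = G \frac{\omega_n}{\sqrt{1-\zeta^2}}
#'       e^{-\zeta\omega_n (t-\tau)} \sin\!\big(\omega_n\sqrt{1-\zeta^2}\,(t-\tau)\big)}
#' for \eqn{t \ge \tau} and zero before the delay \eqn{\tau} (the acoustic
#' arrival time). Optional additive white Gaussian noise is scaled so that the
#' stated SNR holds against the RMS of the noise-free signal over its support
#' (\eqn{t \ge \tau}).
#'
#' @param params a [second_order_params()]; must be underdamped.
#' @param ts sampling interval (s); must satisfy `omega_n * ts < pi` so the
#'   damped oscillation is not aliased.
#' @param n_samples number of samples to generate.
#' @param delay arrival delay in seconds (default 0).
#' @param noise_snr_db signal-to-noise ratio in dB for additive white Gaussian
#'   noise, or `NULL` (default) for a noise-free trace.
#' @param seed integer seed for the noise; the caller's RNG state is restored.
#' @param meta metadata list forwarded to [pa_signal()].
#' @return A [pa_signal()].
#' @examples
#' p <- second_order_params(2 * pi * 2e6, zeta = 0.3, gain = 1e-7)
#' y <- simulate_pa_signal(p, ts = 1 / (30 * 2e6), n_samples = 600)
#' @export
simulate_pa_signal <- function(params, ts, n_samples, delay = 0,
                               noise_snr_db = NULL, seed = NULL,
                               meta = list()) {
  stopifnot(inherits(params, "second_order_params"))
  if (params$zeta >= 1) {
    stop("simulate_pa_signal: unsupported regime, zeta must be < 1 (underdamped)")
  }
  if (params$omega_n * ts >= pi) {
    stop("simulate_pa_signal: aliasing, omega_n * ts must be < pi")
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("simulate_pa_signal: 'n_samples' must be >= 1")
  wn <- params$omega_n
  z <- params$zeta
  wd <- wn * sqrt(1 - z^2)
  t <- (0:(n_samples - 1L)) * ts
  tau <- t - delay
  y <- numeric(n_samples)
  on_support <- tau >= 0
  y[on_support] <- params$gain * (wn / sqrt(1 - z^2)) *
    exp(-z * wn * tau[on_support]) * sin(wd * tau[on_support])
  if (!is.null(noise_snr_db)) {
    if (!any(on_support)) stop("simulate_pa_signal: delay beyond record, no support for SNR")
    rms <- sqrt(mean(y[on_support]^2))
    sigma <- rms / 10^(noise_snr_db / 20)
    y <- y + with_seed(seed, stats::rnorm(n_samples, sd = sigma))
  }
  pa_signal(y, ts = ts, t0 = 0, meta = meta)
}

#' Exact discretization of an underdamped second-order system
#'
#' Builds an order-2 discrete-time state-space model whose eigenvalues are
#' \eqn{\lambda = \exp((-\zeta\omega_n \pm j\omega_n\sqrt{1-\zeta^2})\,t_s)}
#' and whose impulse response samples the continuous-time closed form exactly
#' on the grid `k * ts`. The round trip through [extract_modal_params()]
#' recovers \eqn{(\omega_n, \zeta)} to machine precision.
#'
#' @param params a [second_order_params()]; must be underdamped.
#' @param ts sampling interval in seconds.
#' @return A [state_space_model()] of order 2.
#' @export
discretize <- function(params, ts) {
  stopifnot(inherits(params, "second_order_params"))
  if (!is_underdamped(params)) {
    stop("discretize: params must be underdamped (zeta < 1)")
  }
  if (!is.finite(ts) || ts <= 0) stop("discretize: 'ts' must be positive")
  wn <- params$omega_n
  z <- params$zeta
  wd <- wn * sqrt(1 - z^2)
  r <- exp(-z * wn * ts)
  th <- wd * ts
  # Real rotation-scaling form with eigenvalues r * exp(+/- i * th).
  A <- r * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  # State x_k = K e^{-zeta wn k ts} (sin(wd k ts), cos(wd k ts)); with C = (1, 0)
  # the sampled impulse response is y_k = C A^k x0 for x0 = K (0, 1).
  K <- params$gain * wn / sqrt(1 - z^2)
  B <- matrix(K * c(0, 1), 2, 1)
  C <- matrix(c(1, 0), 1, 2)
  state_space_model(A, B, C, ts = ts)
}
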