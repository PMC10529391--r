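# Output-only N4SID pipeline: Hankel arrangement -> projection onto past
# outputs -> SVD truncation -> observability factor -> state sequences ->
# least-squares regression for {A, C}; B is recovered as the
# impulse-equivalent initial state of the fit window.

# Dominant oscillation frequency (Hz) from the FFT magnitude peak of the
# post-peak segment (the ring-down); used only to choose a decimation factor.
# Restricting to the segment after the absolute peak keeps the estimate
# reliable when most of the record is pre-arrival baseline.
dominant_frequency <- function(y, ts) {
  k0 <- which.max(abs(y))
  seg <- y[k0:min(length(y), k0 + 8192L)]
  seg <- seg - mean(seg)
  n <- length(seg)
  if (n < 8L) return(NA_real_)
  spec <- Mod(stats::fft(seg))[2:floor(n / 2)]
  if (!length(spec) || max(spec) == 0) return(NA_real_)
  (which.max(spec)) / (n * ts)
}

#' Preprocess a PA signal for subspace identification
#'
#' Removes the DC offset and, when the record heavily oversamples the dominant
#' oscillation (as oscilloscope exports do), decimates it so the oscillation
#' carries roughly `target_spp` samples per period. Very long Hankel lags on
#' oversampled data ill-condition the identification; 20-50 samples per period
#' is the practical band.
#'
#' Decimation uses block averaging (a moving-average anti-alias filter aligned
#' with the subsampling grid). A finite-impulse-response average adds zeros
#' but no poles, so the modal content of a damped sinusoid is preserved
#' exactly (each mode \eqn{\lambda^k} maps to \eqn{\lambda^{qk}} up to a
#' constant per mode), while the white-noise variance drops by exactly the
#' decimation factor; recursive anti-alias filters would inject their own
#' dynamics into the ring-down and inflate the apparent model order.
#'
#' @param signal a [pa_signal()].
#' @param target_spp target samples per dominant period after decimation
#'   (default 30).
#' @param decimate if `FALSE`, only the DC offset is removed.
#' @return A [pa_signal()] with updated `ts`; the applied decimation factor is
#'   recorded in `meta$decimation_factor`.
#' @export
preprocess_signal <- function(signal, target_spp = 30, decimate = TRUE) {
  stopifnot(inherits(signal, "pa_signal"))
  # DC offset estimated from the last 10% of the record: for an impulse
  # response the ring-down has decayed there, so the tail shows the true
  # baseline. Subtracting the full-record mean would shift the baseline of a
  # transient record and inject an artificial constant mode (a pole at 1).
  n_tail <- max(1L, floor(length(signal$samples) * 0.1))
  dc <- mean(utils::tail(signal$samples, n_tail))
  y <- signal$samples - dc
  ts <- signal$ts
  q <- 1L
  if (decimate) {
    f_dom <- dominant_frequency(y, ts)
    if (is.finite(f_dom) && f_dom > 0) {
      spp <- 1 / (ts * f_dom)
      q <- max(1L, min(as.integer(floor(spp / target_spp)),
                       as.integer(floor(length(y) / 30))))
      if (q > 1L) {
        n_blocks <- floor(length(y) / q)
        y <- colMeans(matrix(y[1:(n_blocks * q)], nrow = q))
        ts <- ts * q
      }
    }
  }
  meta <- signal$meta
  meta$decimation_factor <- q
  pa_signal(y, ts = ts, t0 = signal$t0, meta = meta)
}

#' N4SID subspace identification of a PA signal
#'
#' Identifies a discrete-time state-space model from a single measured PA
#' trace, treating it as the impulse response of the underlying second-order
#' system. The pipeline is: DC removal and anti-alias decimation
#' ([preprocess_signal()]); windowing from the detected acoustic arrival
#' ([arrival_time()]) through the end of the ring-down; block Hankel
#' arrangement ([build_hankel()]); orthogonal projection of the future outputs
#' onto the past outputs ([orthogonal_project()]; with no measured input the
#' past outputs are the instruments); SVD truncation at the selected order
#' ([estimate_order()]); extended observability factor
#' \eqn{\Gamma_i = U_1 S_1^{1/2}}; state-sequence estimates through
#' pseudo-inverses; and a least-squares solve of the stacked state/output
#' regression for \eqn{A} and \eqn{C}. \eqn{B} is estimated as the
#' impulse-equivalent initial state minimizing
#' \eqn{\sum_k (y_k - C A^k x_0)^2} on the fit window.
#'
#' @param signal a [pa_signal()].
#' @param i number of Hankel block rows, or `"auto"` (default): 20, reduced
#'   when the fit window is short (window length of at least `4 * i` samples is
#'   enforced).
#' @param order model order, or `"auto"` (default) for SVD-gap selection.
#' @param target_spp samples per dominant period after decimation; see
#'   [preprocess_signal()].
#' @param decimate logical; apply anti-alias decimation (default `TRUE`).
#' @param window `"arrival"` (default) to fit from the detected arrival time to
#'   the end of the record, or `"full"` to use the whole record.
#' @param arrival_method,threshold_fraction forwarded to [arrival_time()].
#' @param order_threshold_ratio forwarded to [estimate_order()].
#' @return An object of class `identification_result` with fields `model`
#'   (a [state_space_model()] at the decimated sampling interval),
#'   `singular_values`, `order`, `eigenvalues`, `nrmse_percent`, `modal`
#'   (a [second_order_params()], when extraction succeeds), `stable`,
#'   `y_window`, `y_model`, `decimation_factor` and `arrival_s`.
#' @examples
#' p <- second_order_params(2 * pi * 2e6, 0.25, gain = 1e-7)
#' y <- simulate_pa_signal(p, ts = 1 / (60e6), n_samples = 2000)
#' fit <- n4sid_fit(y)
#' fit$modal$zeta
#' @export
n4sid_fit <- function(signal, i = "auto", order = "auto",
                      target_spp = 30, decimate = TRUE,
                      window = c("arrival", "full"),
                      arrival_method = c("threshold", "first-peak"),
                      threshold_fraction = 0.1,
                      order_threshold_ratio = 1e-2) {
  stopifnot(inherits(signal, "pa_signal"))
  window <- match.arg(window)
  arrival_method <- match.arg(arrival_method)
  if (max(abs(signal$samples - mean(signal$samples))) == 0) {
    stop("n4sid_fit: no dynamics, signal is constant")
  }

  pre <- preprocess_signal(signal, target_spp = target_spp, decimate = decimate)
  ts_eff <- pre$ts

  arrival_s <- NA_real_
  yw <- pre$samples
  if (window == "arrival") {
    arrival_s <- arrival_time(pre, method = arrival_method,
                              threshold_fraction = threshold_fraction)
    k0 <- max(1L, 1L + round((arrival_s - pre$t0) / ts_eff))
    # a decimated block straddling the onset mixes pre-arrival zeros with the
    # ring-down; skip it so the window is purely modal
    if (pre$meta$decimation_factor > 1L) k0 <- min(k0 + 1L, length(pre$samples))
    yw <- pre$samples[k0:length(pre$samples)]
  }

  n_w <- length(yw)
  # keep the Hankel wide (j >> i): deep block rows of a fast ring-down carry
  # little signal, so i is capped at a tenth of the window
  if (identical(i, "auto")) i <- max(2L, min(20L, floor(n_w / 10)))
  i <- as.integer(i)
  if (n_w < 4L * i) {
    stop(sprintf("n4sid_fit: fit window too short, need >= %d samples for i = %d (have %d)",
                 4L * i, i, n_w))
  }

  hank <- build_hankel(yw, i = i)
  Oi <- orthogonal_project(hank$Yf, hank$Yp)
  sv <- svd(Oi)
  singular_values <- sv$d

  n <- if (identical(order, "auto")) {
    estimate_order(singular_values, threshold_ratio = order_threshold_ratio)
  } else as.integer(order)
  if (n < 1L) stop("n4sid_fit: no dynamics, selected model order is 0")
  n <- min(n, length(singular_values))

  U1 <- sv$u[, 1:n, drop = FALSE]
  S1 <- singular_values[1:n]
  Gamma_i <- U1 %*% diag(sqrt(S1), n, n)
  Xi <- pinv_svd(Gamma_i) %*% Oi

  O_next <- orthogonal_project(hank$Yf_minus, hank$Yp_plus)
  Gamma_up <- Gamma_i[1:(i - 1L), , drop = FALSE]
  Xi_next <- pinv_svd(Gamma_up) %*% O_next

  Y_i <- matrix(yw[(i + 1L):(i + hank$j)], nrow = 1L) # block row at time i
  F_mat <- rbind(Xi_next, Y_i)
  theta <- F_mat %*% pinv_svd(Xi)
  A <- theta[1:n, , drop = FALSE]
  C <- theta[n + 1L, , drop = FALSE]

  eigenvalues <- eigen(A, only.values = TRUE)$values
  stable <- all(Mod(eigenvalues) < 1)
  if (!stable) {
    warning("n4sid_fit: identified A has eigenvalues on or outside the unit circle")
  }

  # impulse-equivalent initial state: regressor row k is C A^(k-1)
  Phi <- matrix(0, n_w, n)
  row_k <- C
  for (k in seq_len(n_w)) {
    Phi[k, ] <- row_k
    row_k <- row_k %*% A
  }
  x0 <- qr.solve(qr(Phi), yw)
  B <- matrix(x0, n, 1L)
  y_model <- drop(Phi %*% x0)

  model <- state_space_model(A, B, C, ts = ts_eff)
  fit_nrmse <- nrmse(yw, y_model)

  modal <- tryCatch(
    extract_modal_params(A, ts_eff),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(modal) && is_underdamped(modal)) {
    # scale-match the closed-form unit-gain response on the window
    h_unit <- simulate_pa_signal(
      second_order_params(modal$omega_n, modal$zeta, gain = 1),
      ts = ts_eff, n_samples = n_w)$samples
    denom <- sum(h_unit^2)
    if (denom > 0) modal$gain <- sum(y_model * h_unit) / denom
  }

  structure(list(
    model = model,
    singular_values = singular_values,
    order = n,
    eigenvalues = eigenvalues,
    nrmse_percent = fit_nrmse,
    modal = modal,
    stable = stable,
    y_window = yw,
    y_model = y_model,
    decimation_factor = pre$meta$decimation_factor,
    arrival_s = arrival_s,
    i = i
  ), class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("N4SID identification: order %d, NRMSE = %.2f%%%s\n",
              x$order, x$nrmse_percent, if (x$stable) "" else " [UNSTABLE]"))
  cat("  leading singular values:",
      paste(sprintf("%.3g", utils::head(x$singular_values, 4)), collapse = ", "), "\n")
  if (!is.null(x$modal)) {
    cat(sprintf("  modal: f_n = %.4g MHz, zeta = %.4g\n",
                x$modal$omega_n / (2 * pi * 1e6), x$modal$zeta))
  }
  invisible(x)
}
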