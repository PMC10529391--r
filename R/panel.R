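#' Specification of a synthetic hydrogel panel
#'
#' Describes a panel of synthetic PA signals emulating the nine-hydrogel study
#' design: five PVA concentrations (7, 9, 12, 15, 20%) for molecular-weight
#' class MW1 and four (7, 9, 12, 15%) for MW2. Per sample, the damping ratio
#' rises linearly with concentration and the natural frequency falls along a
#' quadratic, the trends observed across real panels:
#' \deqn{\zeta(c) = \zeta_0 + \zeta_1 c, \qquad
#'       f_n(c) = f_{max} - q\,c^2 \ \mathrm{(MHz)}.}
#' Arrival delays, outer diameters and amplitude scales are taken from the
#' published panel means ([hydrogel_panel_reference()]), so delays lengthen
#' and amplitudes grow with concentration. Signals are generated oversampled
#' (default 600 samples per oscillation period, a scaled-down emulation of a
#' 10 GS/s oscilloscope recording a ~2.25 MHz transducer) and are meant to be
#' decimated by the identification pipeline.
#'
#' @param mw molecular-weight classes to include (`"MW1"`, `"MW2"` or both).
#' @param snr_db additive-noise SNR in dB for every sample (default 20), or
#'   `NULL` for noise-free signals.
#' @param samples_per_period generation oversampling (samples per damped
#'   oscillation period), default 600.
#' @param zeta_intercept,zeta_slope linear damping-ratio trend; defaults 0.10
#'   and 0.02 per percent give zeta from 0.24 (7%) to 0.50 (20%).
#' @param fn_mhz_max,fn_mhz_quad quadratic natural-frequency trend; defaults
#'   3.0 MHz and 0.004 MHz/%^2 give f_n from 2.80 MHz (7%) down to 1.40 MHz
#'   (20%).
#' @param record_span_us common acquisition window in microseconds (every
#'   sample is recorded from 0 to this time, like an oscilloscope with a fixed
#'   window); default 40, which covers the longest arrival plus a fully
#'   decayed ring-down for all panel members.
#' @return An object of class `panel_spec`: a data frame with one row per
#'   sample (`sample_id`, `mw`, `concentration`, `zeta`, `fn_mhz`, `omega_n`,
#'   `gain`, `delay_s`, `D_mm`, `snr_db`, `ts`, `n_samples`).
#' @export
panel_spec <- function(mw = c("MW1", "MW2"), snr_db = 20,
                       samples_per_period = 600,
                       zeta_intercept = 0.10, zeta_slope = 0.02,
                       fn_mhz_max = 3.0, fn_mhz_quad = 0.004,
                       record_span_us = 40) {
  mw <- match.arg(mw, c("MW1", "MW2"), several.ok = TRUE)
  ref <- hydrogel_panel_reference()
  ref <- ref[ref$mw %in% mw, ]
  stopifnot(all(ref$concentration %in% c(7, 9, 12, 15, 20)))
  zeta <- zeta_intercept + zeta_slope * ref$concentration
  if (any(zeta <= 0 | zeta >= 1)) {
    stop("panel_spec: damping-ratio trend leaves the underdamped range (0, 1)")
  }
  fn_mhz <- fn_mhz_max - fn_mhz_quad * ref$concentration^2
  if (any(fn_mhz <= 0)) stop("panel_spec: natural-frequency trend is non-positive")
  omega_n <- 2 * pi * fn_mhz * 1e6
  # gain chosen so the noise-free peak-to-peak amplitude equals the published
  # value: the first extremum of the unit-gain response has height
  # omega_n * exp(-zeta * phi / sqrt(1 - zeta^2)) with phi = atan2(sqrt(1 -
  # zeta^2), zeta), and each following extremum is smaller by
  # exp(-pi * zeta / sqrt(1 - zeta^2))
  s <- sqrt(1 - zeta^2)
  phi <- atan2(s, zeta)
  pp_unit <- omega_n * exp(-zeta * phi / s) * (1 + exp(-pi * zeta / s))
  gain <- ref$amplitude_mV * 1e-3 / pp_unit
  delay_s <- ref$ta_us * 1e-6
  ts <- 1 / (samples_per_period * fn_mhz * 1e6)
  if (any(delay_s + 12 / (zeta * omega_n) > record_span_us * 1e-6)) {
    stop("panel_spec: 'record_span_us' too short to contain the ring-downs")
  }
  n_samples <- ceiling(record_span_us * 1e-6 / ts)
  spec <- data.frame(
    sample_id = sprintf("%s_%02d", ref$mw, ref$concentration),
    mw = ref$mw,
    concentration = ref$concentration,
    zeta = zeta,
    fn_mhz = fn_mhz,
    omega_n = omega_n,
    gain = gain,
    delay_s = delay_s,
    D_mm = ref$D_mm,
    snr_db = if (is.null(snr_db)) NA_real_ else snr_db,
    ts = ts,
    n_samples = as.integer(n_samples),
    stringsAsFactors = FALSE
  )
  class(spec) <- c("panel_spec", "data.frame")
  spec
}

#' Generate a synthetic PA signal panel
#'
#' Simulates one PA trace per sample of a [panel_spec()] through
#' [simulate_pa_signal()] and returns the signals together with the
#' ground-truth parameter table. Runs are reproducible: the same seed yields
#' identical output (per-sample sub-seeds are derived from `seed`).
#'
#' @param spec a [panel_spec()]; default `panel_spec()` (the full nine-sample
#'   panel at 20 dB SNR).
#' @param seed integer seed.
#' @return An object of class `pa_panel`: a list with `signals` (named list of
#'   [pa_signal()]) and `truth` (the spec data frame).
#' @examples
#' pan <- generate_panel(panel_spec(mw = "MW1", snr_db = NULL), seed = 1)
#' names(pan$signals)
#' @export
generate_panel <- function(spec = panel_spec(), seed = 1) {
  stopifnot(inherits(spec, "panel_spec"))
  signals <- lapply(seq_len(nrow(spec)), function(r) {
    simulate_pa_signal(
      second_order_params(spec$omega_n[r], spec$zeta[r], gain = spec$gain[r]),
      ts = spec$ts[r],
      n_samples = spec$n_samples[r],
      delay = spec$delay_s[r],
      noise_snr_db = if (is.na(spec$snr_db[r])) NULL else spec$snr_db[r],
      seed = as.integer(seed) + r,
      meta = list(sample_id = spec$sample_id[r], mw = spec$mw[r],
                  concentration = spec$concentration[r],
                  diameter_mm = spec$D_mm[r])
    )
  })
  names(signals) <- spec$sample_id
  structure(list(signals = signals, truth = as.data.frame(spec)),
            class = "pa_panel")
}

#' @export
print.pa_panel <- function(x, ...) {
  cat(sprintf("Synthetic PA panel: %d samples\n", length(x$signals)))
  print(x$truth[, c("sample_id", "concentration", "zeta", "fn_mhz",
                    "delay_s", "snr_db")])
  invisible(x)
}

#' Write the ground-truth table of a synthetic panel
#'
#' @param panel a [generate_panel()] result.
#' @param path output CSV path.
#' @return The truth data frame, invisibly.
#' @export
write_panel_truth <- function(panel, path) {
  stopifnot(inherits(panel, "pa_panel"))
  utils::write.csv(panel$truth, path, row.names = FALSE)
  invisible(panel$truth)
}

#' Identify every signal of a panel
#'
#' Convenience wrapper running [n4sid_fit()] on each panel member and
#' collecting the recovered modal parameters and fit quality next to the
#' ground truth.
#'
#' @param panel a [generate_panel()] result.
#' @param ... forwarded to [n4sid_fit()].
#' @return A data frame with per-sample `sample_id`, `mw`, `concentration`,
#'   true and estimated `zeta` and `omega_n`, `nrmse_percent`, `order` and
#'   `stable`.
#' @export
identify_panel <- function(panel, ...) {
  stopifnot(inherits(panel, "pa_panel"))
  rows <- lapply(seq_along(panel$signals), function(r) {
    fit <- n4sid_fit(panel$signals[[r]], ...)
    truth <- panel$truth[r, ]
    data.frame(
      sample_id = truth$sample_id,
      mw = truth$mw,
      concentration = truth$concentration,
      zeta_true = truth$zeta,
      zeta_est = if (!is.null(fit$modal)) fit$modal$zeta else NA_real_,
      omega_n_true = truth$omega_n,
      omega_n_est = if (!is.null(fit$modal)) fit$modal$omega_n else NA_real_,
      nrmse_percent = fit$nrmse_percent,
      order = fit$order,
      stable = fit$stable,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
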