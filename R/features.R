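#' Arrival time of the pressure wave
#'
#' Detects the acoustic arrival of a PA trace. The default `"threshold"`
#' method returns the first instant at which the absolute amplitude exceeds
#' `threshold_fraction` times the global absolute peak; the `"first-peak"`
#' method returns the time of the first local extremum of |y| above that
#' level. A detectable event is required: the absolute peak must exceed five
#' times the baseline noise RMS, where the baseline is the first 10% of the
#' record.
#'
#' @param signal a [pa_signal()].
#' @param method `"threshold"` (default) or `"first-peak"`.
#' @param threshold_fraction fraction of the global absolute peak defining the
#'   detection level (default 0.1).
#' @return Arrival time in seconds (on the signal's time axis).
#' @examples
#' p <- second_order_params(2 * pi * 2e6, 0.3, gain = 1e-7)
#' y <- simulate_pa_signal(p, ts = 1e-8, n_samples = 4000, delay = 25.6e-6)
#' arrival_time(y) * 1e6 # ~25.6 us
#' @export
arrival_time <- function(signal, method = c("threshold", "first-peak"),
                         threshold_fraction = 0.1) {
  stopifnot(inherits(signal, "pa_signal"))
  method <- match.arg(method)
  y <- abs(signal$samples)
  peak <- max(y)
  if (peak == 0) stop("arrival_time: no arrival detected (signal is zero)")
  n_base <- max(1L, floor(length(y) * 0.1))
  # the baseline gate only makes sense when the event lies beyond the baseline
  if (which.max(y) > n_base) {
    baseline_rms <- sqrt(mean(signal$samples[1:n_base]^2))
    if (baseline_rms > 0 && peak <= 5 * baseline_rms) {
      stop("arrival_time: no arrival detected (peak does not exceed 5x baseline RMS)")
    }
  }
  level <- threshold_fraction * peak
  k <- if (method == "threshold") {
    which(y > level)[1]
  } else {
    n <- length(y)
    cand <- which(y[2:(n - 1)] > level &
                    y[2:(n - 1)] >= y[1:(n - 2)] &
                    y[2:(n - 1)] >= y[3:n]) + 1L
    cand[1]
  }
  if (is.na(k)) stop("arrival_time: no arrival detected")
  signal$t0 + (k - 1L) * signal$ts
}

#' Peak-to-peak amplitude of a PA signal
#'
#' Maximum minus minimum amplitude within a time window. With `window = NULL`
#' the window runs from the detected arrival time ([arrival_time()]) to the
#' end of the record.
#'
#' @param signal a [pa_signal()].
#' @param window length-2 numeric `c(t_start, t_end)` in seconds, or `NULL`.
#' @return Peak-to-peak amplitude in the signal's amplitude units.
#' @export
peak_to_peak <- function(signal, window = NULL) {
  stopifnot(inherits(signal, "pa_signal"))
  t <- signal_time(signal)
  if (is.null(window)) {
    window <- c(arrival_time(signal), t[length(t)])
  }
  if (length(window) != 2L || window[2] < window[1]) {
    stop("peak_to_peak: 'window' must be c(t_start, t_end) with t_end >= t_start")
  }
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) stop("peak_to_peak: empty window")
  max(signal$samples[sel]) - min(signal$samples[sel])
}

#' Speed of sound from diameter and arrival time
#'
#' `c = D / t_a` with D in millimetres and t_a in microseconds; 1 mm/us equals
#' 1000 m/s.
#'
#' @param D_mm sample outer diameter in mm.
#' @param t_a_us arrival time in microseconds.
#' @return Speed of sound in m/s.
#' @examples
#' speed_of_sound(39.70, 25.60) # ~1551 m/s
#' @export
speed_of_sound <- function(D_mm, t_a_us) {
  if (any(!is.finite(D_mm)) || any(D_mm <= 0)) stop("speed_of_sound: 'D_mm' must be positive")
  if (any(!is.finite(t_a_us)) || any(t_a_us <= 0)) stop("speed_of_sound: 't_a_us' must be positive")
  D_mm / t_a_us * 1000
}

#' Time-domain PA feature set of a signal
#'
#' Computes the standard time-domain descriptors of a PA trace: arrival time,
#' peak-to-peak amplitude over the post-arrival window, and, when the sample
#' diameter is known, the speed of sound.
#'
#' @param signal a [pa_signal()]; `meta$diameter_mm` supplies `D_mm` when the
#'   argument is missing.
#' @param D_mm outer diameter in mm, or `NA`.
#' @param method,threshold_fraction forwarded to [arrival_time()].
#' @return An object of class `pa_features`: a list with `amplitude_pp` (V),
#'   `amplitude_mV`, `t_a_s`, `t_a_us`, `c_m_s`, `D_mm` and `method`.
#' @export
pa_features <- function(signal, D_mm = NULL,
                        method = c("threshold", "first-peak"),
                        threshold_fraction = 0.1) {
  stopifnot(inherits(signal, "pa_signal"))
  method <- match.arg(method)
  if (is.null(D_mm)) D_mm <- signal$meta$diameter_mm %||% NA_real_
  t_a <- arrival_time(signal, method = method,
                      threshold_fraction = threshold_fraction)
  app <- peak_to_peak(signal, window = c(t_a, max(signal_time(signal))))
  c_ms <- if (is.finite(D_mm)) speed_of_sound(D_mm, t_a * 1e6) else NA_real_
  structure(list(
    amplitude_pp = app, amplitude_mV = app * 1e3,
    t_a_s = t_a, t_a_us = t_a * 1e6,
    c_m_s = c_ms, D_mm = D_mm, method = method
  ), class = "pa_features")
}

#' @export
print.pa_features <- function(x, ...) {
  cat(sprintf("PA features (%s arrival): t_a = %.4g us, A_pp = %.4g mV, c = %s m/s\n",
              x$method, x$t_a_us, x$amplitude_mV,
              if (is.finite(x$c_m_s)) sprintf("%.0f", x$c_m_s) else "NA"))
  invisible(x)
}

#' Write a panel feature table
#'
#' Writes a CSV with columns `sample_id, MW, concentration, D_mm, ta_us,
#' c_m_s, amplitude_mV` (one row per sample), mirroring the usual layout of
#' published phantom-panel tables.
#'
#' @param features a list of [pa_features()] results.
#' @param meta a data frame (or list of lists) with per-sample `sample_id`,
#'   `mw` and `concentration`.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_feature_table <- function(features, meta, path) {
  meta <- as.data.frame(meta)
  stopifnot(length(features) == nrow(meta))
  df <- data.frame(
    sample_id = meta$sample_id,
    MW = meta$mw,
    concentration = meta$concentration,
    D_mm = vapply(features, function(f) f$D_mm, numeric(1)),
    ta_us = vapply(features, function(f) f$t_a_us, numeric(1)),
    c_m_s = round(vapply(features, function(f) f$c_m_s, numeric(1))),
    amplitude_mV = vapply(features, function(f) f$amplitude_mV, numeric(1))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Reference feature table of the nine-hydrogel panel
#'
#' Printed physical and optoacoustic variables of the nine PVA hydrogels
#' (five concentrations at molecular-weight class MW1, four at MW2): outer
#' diameter D (mm), arrival time t_a (us), speed of sound c (m/s) and
#' peak-to-peak amplitude A (mV). These published means serve as anchor
#' inputs for unit-consistency checks and for configuring realistic synthetic
#' panels.
#'
#' @return A data frame with columns `mw`, `concentration`, `D_mm`, `ta_us`,
#'   `c_m_s`, `amplitude_mV`.
#' @export
hydrogel_panel_reference <- function() {
  data.frame(
    mw = c(rep("MW1", 5), rep("MW2", 4)),
    concentration = c(7, 9, 12, 15, 20, 7, 9, 12, 15),
    D_mm = c(39.70, 43.16, 45.00, 46.22, 46.62, 40.20, 40.54, 43.84, 43.89),
    ta_us = c(25.60, 28.18, 28.45, 30.14, 30.82, 26.39, 27.08, 28.63, 28.67),
    c_m_s = c(1551, 1532, 1582, 1534, 1513, 1523, 1497, 1531, 1531),
    amplitude_mV = c(0.87, 1.51, 1.70, 4.07, 6.66, 1.50, 1.59, 3.41, 4.06)
  )
}
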