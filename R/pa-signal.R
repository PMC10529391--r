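#' Photoacoustic signal container
#'
#' A `pa_signal` is a uniformly sampled pressure trace: an amplitude vector
#' (volts), a sampling interval `ts` (seconds), the time of the first sample
#' `t0`, and optional sample metadata (molecular-weight class, PVA
#' concentration, outer diameter). The time axis is exactly
#' `t_k = t0 + k * ts`.
#'
#' @param samples numeric vector of amplitudes in volts.
#' @param ts sampling interval in seconds; must be positive.
#' @param t0 time of the first sample in seconds.
#' @param meta optional named list of sample metadata; recognized entries are
#'   `mw` (`"MW1"` or `"MW2"`), `concentration` (PVA percent), `diameter_mm`
#'   (outer diameter D) and `sample_id`.
#' @return An object of class `pa_signal`.
#' @examples
#' y <- pa_signal(sin(2 * pi * 0.05 * (0:99)), ts = 1e-8)
#' length(signal_time(y))
#' @export
pa_signal <- function(samples, ts, t0 = 0, meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("pa_signal: 'samples' must be non-empty")
  if (!is.numeric(ts) || length(ts) != 1L || !is.finite(ts) || ts <= 0) {
    stop("pa_signal: 'ts' must be a positive scalar (seconds)")
  }
  if (!is.list(meta)) stop("pa_signal: 'meta' must be a list")
  structure(
    list(samples = samples, ts = ts, t0 = t0, meta = meta),
    class = "pa_signal"
  )
}

#' Time axis of a PA signal
#'
#' @param signal a [pa_signal()].
#' @return Numeric vector `t0 + (0:(n-1)) * ts` in seconds.
#' @export
signal_time <- function(signal) {
  stopifnot(inherits(signal, "pa_signal"))
  signal$t0 + (seq_along(signal$samples) - 1) * signal$ts
}

#' @export
print.pa_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("PA signal: %d samples, ts = %.4g s (%.4g MS/s), span %.4g us\n",
              n, x$ts, 1e-6 / x$ts, n * x$ts * 1e6))
  if (length(x$meta)) {
    keys <- intersect(c("sample_id", "mw", "concentration", "diameter_mm"),
                      names(x$meta))
    if (length(keys)) {
      cat("  meta:", paste(sprintf("%s=%s", keys, unlist(x$meta[keys])),
                           collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
plot.pa_signal <- function(x, ..., xlab = "time (us)", ylab = "amplitude (V)") {
  plot(signal_time(x) * 1e6, x$samples, type = "l",
       xlab = xlab, ylab = ylab, ...)
}
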