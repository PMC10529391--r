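#' Read a sampled PA signal from a two-column table
#'
#' Reads an oscilloscope-style export: two numeric columns (time in seconds,
#' amplitude in volts), comma- or tab-separated, header optional. The time
#' grid must be uniform within a relative tolerance of 1e-6 of the median
#' step; the sampling interval is inferred from the median time step.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @param meta metadata list forwarded to [pa_signal()].
#' @return A [pa_signal()].
#' @export
read_signal <- function(path, dialect = c("auto", "csv", "tsv"), meta = list()) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  sep <- switch(dialect,
                csv = ",",
                tsv = "\t",
                auto = if (grepl("\t", first)) "\t" else ",")
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(path, sep = sep, header = has_header)
  if (ncol(df) < 2L) stop("read_signal: expected two columns (time, amplitude)")
  if (nrow(df) < 10L) stop("read_signal: fewer than 10 rows")
  t <- as.numeric(df[[1]])
  y <- as.numeric(df[[2]])
  if (any(is.na(t)) || any(is.na(y))) stop("read_signal: non-numeric entries")
  dt <- diff(t)
  ts <- stats::median(dt)
  if (ts <= 0) stop("read_signal: time column is not increasing")
  if (max(abs(dt - ts)) > 1e-6 * ts) {
    stop("read_signal: non-uniform time grid (beyond 1e-6 relative tolerance)")
  }
  pa_signal(y, ts = ts, t0 = t[1], meta = meta)
}

#' Write a PA signal as a two-column CSV
#'
#' Columns `time_s, amplitude_V`, with 15 significant digits so a read/write
#' round trip preserves the samples to at least 12 significant digits.
#'
#' @param signal a [pa_signal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "pa_signal"))
  t <- signal_time(signal)
  lines <- c("time_s,amplitude_V",
             sprintf("%.15g,%.15g", t, signal$samples))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the tunable knobs of the analysis pipeline into a validated,
#' serializable object. The file format is a flat key-value YAML subset with a
#' `config_version` field.
#'
#' @param target_spp decimation target in samples per dominant period
#'   (range 4-5000, default 30).
#' @param hankel_i Hankel block rows (default 20).
#' @param order `"auto"` or a fixed positive integer.
#' @param arrival_method `"threshold"` or `"first-peak"`.
#' @param threshold_fraction arrival detection level as a fraction of the
#'   global peak, in (0, 1).
#' @param mc_photons photons per Monte-Carlo forward run (>= 1000).
#' @param seed integer seed.
#' @param out_dir output directory for CLI artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(target_spp = 30, hankel_i = 20, order = "auto",
                       arrival_method = "threshold", threshold_fraction = 0.1,
                       mc_photons = 1e5, seed = 1, out_dir = ".") {
  if (!is.numeric(target_spp) || target_spp < 4 || target_spp > 5000) {
    stop("run_config: 'target_spp' must be in [4, 5000]")
  }
  if (!is.numeric(hankel_i) || hankel_i < 2) stop("run_config: 'hankel_i' must be >= 2")
  if (!identical(order, "auto") && (!is.numeric(order) || order < 1)) {
    stop("run_config: 'order' must be \"auto\" or a positive integer")
  }
  if (!arrival_method %in% c("threshold", "first-peak")) {
    stop("run_config: unknown arrival method")
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    stop("run_config: 'threshold_fraction' must be in (0, 1)")
  }
  if (!is.numeric(mc_photons) || mc_photons < 1000) {
    stop("run_config: 'mc_photons' must be >= 1000")
  }
  structure(list(
    config_version = 1L,
    target_spp = target_spp,
    hankel_i = as.integer(hankel_i),
    order = if (identical(order, "auto")) "auto" else as.integer(order),
    arrival_method = arrival_method,
    threshold_fraction = threshold_fraction,
    mc_photons = as.integer(mc_photons),
    seed = as.integer(seed),
    out_dir = out_dir
  ), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$config_version)) stop("read_run_config: missing config_version")
  do.call(run_config, vals[setdiff(names(vals), "config_version")])
}
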