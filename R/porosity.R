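#' Bin pore diameters into a fixed histogram
#'
#' Counts pore diameters into half-open decade bins `[lo, hi)`; the default
#' edges are 0, 10, ..., 80 um, the standard grouping for hydrogel pore-size
#' histograms (small diameters 0-30 um, larger diameters 30-80 um). Diameters
#' outside `[min(edges), max(edges))` are not binned; they are counted in the
#' `out_of_range` field.
#'
#' @param diameters_um numeric vector of pore diameters in micrometres.
#' @param edges_um strictly increasing bin edges in micrometres.
#' @param n_samples_averaged how many sample cuts the diameters were pooled
#'   from (metadata only).
#' @return An object of class `pore_histogram` with fields `bin_edges`,
#'   `counts`, `mids`, `out_of_range` and `n_samples_averaged`.
#' @examples
#' bin_pores(c(5, 15, 15, 75))$counts
#' @export
bin_pores <- function(diameters_um, edges_um = seq(0, 80, by = 10),
                      n_samples_averaged = 1L) {
  d <- as.numeric(diameters_um)
  edges <- as.numeric(edges_um)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("bin_pores: 'edges_um' must be strictly increasing")
  }
  in_range <- is.finite(d) & d >= edges[1] & d < edges[length(edges)]
  idx <- findInterval(d[in_range], edges) # [lo, hi) by default
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(
    bin_edges = edges,
    counts = counts,
    mids = (edges[-1] + edges[-length(edges)]) / 2,
    out_of_range = sum(!in_range),
    n_samples_averaged = as.integer(n_samples_averaged)
  ), class = "pore_histogram")
}

#' @export
print.pore_histogram <- function(x, ...) {
  cat("Pore histogram (um):\n")
  lab <- sprintf("%g-%g", x$bin_edges[-length(x$bin_edges)], x$bin_edges[-1])
  print(stats::setNames(x$counts, lab))
  if (x$out_of_range > 0) cat("  out of range:", x$out_of_range, "\n")
  invisible(x)
}

#' Lognormal fit of a pore-size histogram
#'
#' Nonlinear least squares of `scale * dlnorm(mid; mu, sigma)` against the
#' bin counts at the bin midpoints (the histogram curve is fitted, not the raw
#' diameters). Starting values come from the count-weighted lognormal moments.
#'
#' @param hist a [bin_pores()] histogram with at least 4 non-empty bins.
#' @return An object of class `lognormal_fit` with fields `mu`, `sigma`,
#'   `scale`, `r_squared` and `fitted`.
#' @export
fit_lognormal <- function(hist) {
  stopifnot(inherits(hist, "pore_histogram"))
  if (sum(hist$counts > 0) < 4L) {
    stop("fit_lognormal: need at least 4 non-empty bins")
  }
  mids <- hist$mids
  counts <- hist$counts
  w <- counts / sum(counts)
  mu0 <- sum(w * log(mids))
  sigma0 <- max(sqrt(sum(w * (log(mids) - mu0)^2)), 0.05)
  scale0 <- sum(counts) * mean(diff(hist$bin_edges))
  df <- data.frame(x = mids, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ scale * stats::dlnorm(x, meanlog = mu, sdlog = sigma),
      data = df,
      start = list(scale = scale0, mu = mu0, sigma = sigma0),
      lower = c(1e-12, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("fit_lognormal: did not converge: ",
                             conditionMessage(e))
  )
  est <- stats::coef(fit)
  resid <- counts - stats::fitted(fit)
  ss_tot <- sum((counts - mean(counts))^2)
  structure(list(
    mu = unname(est["mu"]),
    sigma = unname(est["sigma"]),
    scale = unname(est["scale"]),
    r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
    fitted = as.numeric(stats::fitted(fit))
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("LogNormal fit: mu = %.4g, sigma = %.4g (median %.4g um), R^2 = %.4f\n",
              x$mu, x$sigma, exp(x$mu), x$r_squared))
  invisible(x)
}

#' Bulk density
#'
#' `rho = m / V`, from Archimedes-principle mass and volume measurements.
#'
#' @param mass_g mass in grams.
#' @param volume_cm3 volume in cubic centimetres (`> 0`).
#' @return Density in g/cm^3.
#' @export
bulk_density <- function(mass_g, volume_cm3) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0)) {
    stop("bulk_density: 'volume_cm3' must be positive")
  }
  mass_g / volume_cm3
}

#' Young's modulus from a tensile measurement
#'
#' `E = sigma / epsilon`.
#'
#' @param stress_kPa applied stress in kPa.
#' @param strain dimensionless strain (`> 0`).
#' @return Elastic modulus in kPa.
#' @export
elastic_modulus <- function(stress_kPa, strain) {
  if (any(!is.finite(strain)) || any(strain <= 0)) {
    stop("elastic_modulus: 'strain' must be positive")
  }
  stress_kPa / strain
}

#' PVA powder weight for a target gel concentration
#'
#' Weight of PVA powder for a given concentration and water volume:
#' `W = concentration * volume / 100` (7% in 150 mL gives 10.5). The result is
#' labeled "mg" to match the published recipe, although the magnitude is
#' physically consistent with grams; the published unit is reproduced as
#' printed.
#'
#' @param concentration_pct PVA concentration in percent (`> 0` or 0).
#' @param water_volume_ml water volume in mL (`> 0`).
#' @return Weight in the recipe's printed unit ("mg").
#' @examples
#' pva_weight(7, 150) # 10.5
#' @export
pva_weight <- function(concentration_pct, water_volume_ml) {
  if (any(!is.finite(concentration_pct)) || any(concentration_pct < 0)) {
    stop("pva_weight: 'concentration_pct' must be >= 0")
  }
  if (any(!is.finite(water_volume_ml)) || any(water_volume_ml <= 0)) {
    stop("pva_weight: 'water_volume_ml' must be positive")
  }
  concentration_pct * water_volume_ml / 100
}

#' Read pore diameters from a single-column CSV
#'
#' @param path CSV path; one numeric column of diameters in micrometres
#'   (header optional).
#' @return Numeric vector of diameters.
#' @export
read_pore_diameters <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  df <- utils::read.csv(path, header = has_header)
  as.numeric(df[[1]])
}

#' Write a pore histogram and its lognormal fit
#'
#' Writes the binned counts as CSV and, when a fit is supplied, a JSON summary
#' next to it.
#'
#' @param hist a [bin_pores()] histogram.
#' @param path output CSV path.
#' @param fit optional [fit_lognormal()] result; written to
#'   `paste0(path, ".json")`.
#' @return The histogram data frame, invisibly.
#' @export
write_pore_histogram <- function(hist, path, fit = NULL) {
  stopifnot(inherits(hist, "pore_histogram"))
  df <- data.frame(
    bin_lo_um = hist$bin_edges[-length(hist$bin_edges)],
    bin_hi_um = hist$bin_edges[-1],
    count = hist$counts
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(fit)) {
    jsonlite::write_json(
      list(mu = fit$mu, sigma = fit$sigma, scale = fit$scale,
           r_squared = fit$r_squared, out_of_range = hist$out_of_range),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
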