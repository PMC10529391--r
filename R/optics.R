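#' Integrating-sphere measurement
#'
#' Detected powers from the five-beam integrating-sphere protocol: `Pd`
#' (diffuse-diffuse reflection reference), `Pr` (directional-diffuse
#' reflection), `Pt` (directional-diffuse transmission), `Pcoh` (unscattered
#' transmitted power) and `Po` (incident power), together with the sphere wall
#' reflection coefficient and the slab thickness.
#'
#' @param Pd,Pr,Pt,Pcoh,Po detected powers (any consistent unit, all `>= 0`).
#' @param m_wall sphere wall reflection coefficient in (0, 1]; default 0.98.
#' @param thickness_um slab thickness in micrometres.
#' @return An object of class `sphere_measurement`.
#' @export
sphere_measurement <- function(Pd, Pr, Pt, Pcoh, Po, m_wall = 0.98,
                               thickness_um = 100) {
  p <- c(Pd = Pd, Pr = Pr, Pt = Pt, Pcoh = Pcoh, Po = Po)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("sphere_measurement: powers must be finite and >= 0")
  }
  if (!is.finite(m_wall) || m_wall <= 0 || m_wall > 1) {
    stop("sphere_measurement: 'm_wall' must be in (0, 1]")
  }
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("sphere_measurement: 'thickness_um' must be positive")
  }
  structure(list(Pd = Pd, Pr = Pr, Pt = Pt, Pcoh = Pcoh, Po = Po,
                 m_wall = m_wall, thickness_um = thickness_um),
            class = "sphere_measurement")
}

#' Integrating-sphere reflectance and transmittance
#'
#' Directional-diffuse reflectance `Rcd = m * Pr / Pd`, directional-diffuse
#' transmittance `Tcd = m * Pt / Pd`, and coherent transmittance
#' `Tc = Pcoh / Po`, where `m` is the sphere wall reflection coefficient.
#'
#' @param meas a [sphere_measurement()].
#' @return A single number.
#' @examples
#' m <- sphere_measurement(Pd = 1, Pr = 0.449, Pt = 0.48, Pcoh = 0, Po = 1)
#' reflectance_cd(m)
#' @export
reflectance_cd <- function(meas) {
  stopifnot(inherits(meas, "sphere_measurement"))
  if (meas$Pd == 0) stop("reflectance_cd: 'Pd' is zero")
  meas$m_wall * meas$Pr / meas$Pd
}

#' @rdname reflectance_cd
#' @export
transmittance_cd <- function(meas) {
  stopifnot(inherits(meas, "sphere_measurement"))
  if (meas$Pd == 0) stop("transmittance_cd: 'Pd' is zero")
  meas$m_wall * meas$Pt / meas$Pd
}

#' @rdname reflectance_cd
#' @export
transmittance_coherent <- function(meas) {
  stopifnot(inherits(meas, "sphere_measurement"))
  if (meas$Po == 0) stop("transmittance_coherent: 'Po' is zero")
  meas$Pcoh / meas$Po
}

#' Optical properties of a turbid slab
#'
#' @param mu_a absorption coefficient (cm^-1, `>= 0`).
#' @param mu_s scattering coefficient (cm^-1, `>= 0`).
#' @param g scattering anisotropy factor (mean cosine), in (-1, 1).
#' @return An object of class `optical_properties` with the derived reduced
#'   scattering coefficient `mu_s_prime = mu_s * (1 - g)`.
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  if (!is.finite(mu_a) || mu_a < 0) stop("optical_properties: 'mu_a' must be >= 0")
  if (!is.finite(mu_s) || mu_s < 0) stop("optical_properties: 'mu_s' must be >= 0")
  if (!is.finite(g) || g <= -1 || g >= 1) stop("optical_properties: 'g' must be in (-1, 1)")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g,
                 mu_s_prime = reduced_scattering(mu_s, g)),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties: mu_a = %.4g cm^-1, mu_s = %.4g cm^-1, g = %.4g, mu_s' = %.4g cm^-1\n",
              x$mu_a, x$mu_s, x$g, x$mu_s_prime))
  invisible(x)
}

#' Reduced scattering coefficient
#'
#' `mu_s' = mu_s * (1 - g)`.
#'
#' @param mu_s scattering coefficient (cm^-1).
#' @param g anisotropy factor.
#' @return Reduced scattering coefficient (cm^-1).
#' @examples
#' reduced_scattering(51.82, 0.80) # 10.364
#' @export
reduced_scattering <- function(mu_s, g) {
  mu_s * (1 - g)
}

#' Monte-Carlo photon transport through a homogeneous slab
#'
#' Minimal forward model for the inverse determination of slab optical
#' properties: photons enter an index-matched homogeneous slab at normal
#' incidence, propagate with exponential free paths of mean `1/(mu_a + mu_s)`,
#' are absorbed at an interaction with probability `mu_a / (mu_a + mu_s)` and
#' otherwise scatter with a Henyey-Greenstein phase function of anisotropy
#' `g`. Photons leaving the rear face without ever scattering are counted as
#' coherent transmittance (which converges to the Beer-Lambert value
#' `exp(-(mu_a + mu_s) d)`); scattered photons leaving the rear and front
#' faces give the diffuse transmittance and reflectance. No sphere geometry,
#' specular port or refractive-index mismatch is modeled.
#'
#' @param props an [optical_properties()].
#' @param thickness_um slab thickness in micrometres.
#' @param n_photons number of photons (`>= 1000`).
#' @param seed integer seed; the caller's RNG state is restored.
#' @return A list with fractions `R_diffuse`, `T_diffuse`, `T_coherent`,
#'   `absorbed` (summing to 1 exactly over `n_photons`) and `n_photons`.
#' @export
mc_forward_slab <- function(props, thickness_um, n_photons = 1e5, seed = NULL) {
  stopifnot(inherits(props, "optical_properties"))
  n_photons <- as.integer(n_photons)
  if (n_photons < 1000L) stop("mc_forward_slab: 'n_photons' must be >= 1000")
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("mc_forward_slab: 'thickness_um' must be positive")
  }
  d <- thickness_um * 1e-4 # cm
  mu_a <- props$mu_a; mu_s <- props$mu_s; g <- props$g
  mu_t <- mu_a + mu_s
  if (mu_t == 0) {
    return(list(R_diffuse = 0, T_diffuse = 0, T_coherent = 1, absorbed = 0,
                n_photons = n_photons))
  }
  p_abs <- mu_a / mu_t

  with_seed(seed, {
    n_R <- n_Td <- n_Tc <- n_A <- 0L
    z <- numeric(n_photons)
    ux <- numeric(n_photons); uy <- numeric(n_photons)
    uz <- rep(1, n_photons)
    scattered <- logical(n_photons)
    while (length(z)) {
      m <- length(z)
      z <- z + uz * (-log(stats::runif(m)) / mu_t)
      out_t <- z >= d
      out_r <- z <= 0 # only reachable after a scattering event (uz = 1 until then)
      n_Tc <- n_Tc + sum(out_t & !scattered)
      n_Td <- n_Td + sum(out_t & scattered)
      n_R <- n_R + sum(out_r & !out_t)
      keep <- !(out_t | out_r)
      if (!any(keep)) break
      z <- z[keep]; ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]
      scattered <- scattered[keep]
      m <- length(z)
      absorbed <- stats::runif(m) < p_abs
      n_A <- n_A + sum(absorbed)
      keep <- !absorbed
      if (!any(keep)) break
      z <- z[keep]; ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]
      scattered <- rep(TRUE, length(z))
      m <- length(z)
      # Henyey-Greenstein polar angle, uniform azimuth
      ct <- if (g == 0) {
        2 * stats::runif(m) - 1
      } else {
        (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * stats::runif(m)))^2) / (2 * g)
      }
      ct <- pmin(1, pmax(-1, ct))
      st <- sqrt(1 - ct^2)
      phi <- 2 * pi * stats::runif(m)
      cp <- cos(phi); sp <- sin(phi)
      near_pole <- abs(uz) > 0.99999
      den <- sqrt(pmax(1e-30, 1 - uz^2))
      nx <- st * (ux * uz * cp - uy * sp) / den + ux * ct
      ny <- st * (uy * uz * cp + ux * sp) / den + uy * ct
      nz <- -den * st * cp + uz * ct
      nx[near_pole] <- (st * cp)[near_pole]
      ny[near_pole] <- (st * sp)[near_pole]
      nz[near_pole] <- (sign(uz) * ct)[near_pole]
      ux <- nx; uy <- ny; uz <- nz
    }
    list(R_diffuse = n_R / n_photons,
         T_diffuse = n_Td / n_photons,
         T_coherent = n_Tc / n_photons,
         absorbed = n_A / n_photons,
         n_photons = n_photons)
  })
}

#' Inverse Monte-Carlo estimation of slab optical properties
#'
#' Recovers `(mu_a, mu_s, g)` from a measured
#' (reflectance, transmittance, coherent-transmittance) triplet by Nelder-Mead
#' (downhill simplex) minimization of the squared residuals between the
#' [mc_forward_slab()] outputs and the measurements. Every forward evaluation
#' reuses the same random-number seed (common random numbers), so the
#' objective and the returned estimate are deterministic for a given seed and
#' starting simplex. Parameters are optimized on transformed scales
#' (log for the coefficients, atanh for `g`) so the physical bounds hold by
#' construction.
#'
#' With only two informative observables (a panel whose coherent component is
#' negligible), the three-parameter problem is under-determined; `fix_g` fixes
#' the anisotropy and fits `(mu_a, mu_s)` only. `fix_mu_s = 0` switches to the
#' exact Beer-Lambert inverse `mu_a = -log(Tc) / d`.
#'
#' @param Rcd,Tcd,Tc measured triplet, each in `[0, 1]`.
#' @param thickness_um slab thickness in micrometres.
#' @param fix_g fixed anisotropy (in (-1, 1)), or `NULL` to fit it.
#' @param fix_mu_s fixed scattering coefficient, or `NULL` to fit it.
#' @param n_photons photons per forward evaluation (default 1e5).
#' @param seed seed shared by all forward evaluations (default 1).
#' @param start starting values `c(mu_a, mu_s, g)` for the simplex.
#' @param max_iter,reltol Nelder-Mead iteration cap and relative tolerance on
#'   the residual.
#' @return A list with `props` (an [optical_properties()], or `NULL` when the
#'   input is degenerate), `residual`, `converged`, and `flag` (`"ok"`,
#'   `"max-iterations"` or `"diverging-absorption"`).
#' @export
invert_optical_props <- function(Rcd, Tcd, Tc, thickness_um,
                                 fix_g = NULL, fix_mu_s = NULL,
                                 n_photons = 1e5, seed = 1,
                                 start = c(0.5, 20, 0.7),
                                 max_iter = 200, reltol = 1e-4) {
  obs <- c(Rcd, Tcd, Tc)
  if (any(!is.finite(obs)) || any(obs < 0) || any(obs > 1)) {
    stop("invert_optical_props: measured triplet must lie in [0, 1]")
  }
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("invert_optical_props: 'thickness_um' must be positive")
  }
  d <- thickness_um * 1e-4 # cm

  if (all(obs == 0)) {
    return(list(props = NULL, residual = NA_real_, converged = FALSE,
                flag = "diverging-absorption"))
  }
  if (!is.null(fix_mu_s) && fix_mu_s == 0) {
    if (Tc <= 0) {
      return(list(props = NULL, residual = NA_real_, converged = FALSE,
                  flag = "diverging-absorption"))
    }
    props <- optical_properties(-log(Tc) / d, 0, fix_g %||% 0)
    return(list(props = props, residual = 0, converged = TRUE, flag = "ok"))
  }

  fit_g <- is.null(fix_g)
  fit_mu_s <- is.null(fix_mu_s)
  par0 <- c(log(max(start[1], 1e-6)),
            if (fit_mu_s) log(max(start[2], 1e-6)),
            if (fit_g) atanh(start[3]))
  unpack <- function(p) {
    mu_a <- exp(p[1])
    mu_s <- if (fit_mu_s) exp(p[2]) else fix_mu_s
    g <- if (fit_g) tanh(p[length(p)]) else fix_g
    optical_properties(mu_a, mu_s, g)
  }
  objective <- function(p) {
    fw <- mc_forward_slab(unpack(p), thickness_um, n_photons = n_photons,
                          seed = seed)
    (fw$R_diffuse - Rcd)^2 + (fw$T_diffuse - Tcd)^2 + (fw$T_coherent - Tc)^2
  }
  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = reltol))
  list(props = unpack(opt$par),
       residual = opt$value,
       converged = opt$convergence == 0,
       flag = if (opt$convergence == 0) "ok" else "max-iterations")
}

#' Read integrating-sphere measurements
#'
#' Reads a CSV with columns `sample_id, Pd, Pr, Pt, Pcoh, Po, thickness_um`
#' (one row per sample) into a list of [sphere_measurement()] objects.
#'
#' @param path CSV path.
#' @param m_wall sphere wall reflection coefficient applied to all rows.
#' @return Named list of `sphere_measurement` objects (names = sample ids).
#' @export
read_sphere_measurements <- function(path, m_wall = 0.98) {
  df <- utils::read.csv(path)
  need <- c("sample_id", "Pd", "Pr", "Pt", "Pcoh", "Po", "thickness_um")
  if (!all(need %in% names(df))) {
    stop("read_sphere_measurements: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(r) {
    sphere_measurement(df$Pd[r], df$Pr[r], df$Pt[r], df$Pcoh[r], df$Po[r],
                       m_wall = m_wall, thickness_um = df$thickness_um[r])
  })
  names(out) <- df$sample_id
  out
}
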