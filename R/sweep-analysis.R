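# Reduction of raw sweep and compression records to model parameters.

#' Detect the linear viscoelastic (LVE) strain limit
#'
#' The LVE region is the strain-amplitude range over which the storage modulus
#' is independent of amplitude. The reference level is the mean of G' over the
#' lowest decade of tested strains; the limit is the largest strain amplitude
#' up to which G' stays within `tolerance_fraction` of that level. If the
#' tolerance is never exceeded the maximum tested strain is returned; if even
#' the second point departs, the first strain is returned (no plateau).
#'
#' @param sweep A [strain_sweep()] with at least 4 points.
#' @param tolerance_fraction Allowed relative departure of G' from the plateau
#'   level, in (0, 0.5); default 0.05.
#' @return LVE limit as a strain amplitude in percent.
#' @export
detect_lve_limit <- function(sweep, tolerance_fraction = 0.05) {
  stopifnot(inherits(sweep, "strain_sweep"))
  if (length(sweep$strain_pct) < 4) {
    stop_input("LVE detection needs at least 4 strain points")
  }
  check_numeric(tolerance_fraction, "tolerance_fraction", len = 1)
  if (tolerance_fraction <= 0 || tolerance_fraction >= 0.5) {
    stop_input("'tolerance_fraction' must lie in (0, 0.5)")
  }
  low <- sweep$strain_pct <= min(sweep$strain_pct) * 10
  ref <- mean(sweep$storage_pa[low])
  outside <- abs(sweep$storage_pa - ref) > tolerance_fraction * ref
  first_out <- which(outside)[1]
  if (is.na(first_out)) {
    return(max(sweep$strain_pct))
  }
  sweep$strain_pct[max(first_out - 1, 1)]
}

#' Detect the inertial cutoff frequency of a sweep
#'
#' At high frequency the rotational inertia of sample and instrument corrupts
#' the torque-displacement relation and the measured modulus collapses. The
#' cutoff is the last frequency before the monotone decline that leads into
#' a persistent drop of G' below `(1 - drop_fraction)` times the running
#' maximum with no recovery;
#' `NA` if no such persistent drop exists (the full range is usable). A
#' transient single-point dip that recovers is not a cutoff.
#'
#' @param sweep A [frequency_sweep()] or [modulus_spectrum()] with at least 4
#'   frequency points.
#' @param drop_fraction Relative drop from the running maximum that marks
#'   inertial contamination; default 0.1.
#' @return The cutoff frequency in Hz, or `NA_real_` when no drop is found.
#' @export
detect_inertial_cutoff <- function(sweep, drop_fraction = 0.1) {
  stopifnot(inherits(sweep, c("frequency_sweep", "modulus_spectrum")))
  f <- sweep$frequency_hz
  g <- sweep$storage_pa
  if (length(f) < 4) {
    stop_input("cutoff detection needs at least 4 frequency points")
  }
  check_numeric(drop_fraction, "drop_fraction", positive = TRUE, len = 1)
  run_max <- cummax(g)
  below <- g < (1 - drop_fraction) * run_max
  # persistent drop: every point from some index onward is below threshold
  persistent <- rev(cumprod(rev(below))) > 0
  if (!persistent[length(persistent)] || !any(persistent)) {
    return(NA_real_)
  }
  start <- which(persistent)[1]
  # the collapse contaminates a shoulder of points that decline toward the
  # threshold crossing before falling below it; walk back over that monotone
  # decline so the cutoff is the last point before the shoulder. (A global
  # pre-collapse argmax is not used: on a near-flat noisy spectrum it can
  # land on an arbitrary early grid point and discard the usable band.)
  i <- start - 1
  while (i > 1 && g[i] < g[i - 1]) i <- i - 1
  f[i]
}

#' Truncate a sweep at the inertial cutoff
#'
#' Keeps every point at or below `cutoff_hz`; points below the cutoff are
#' never removed. A missing cutoff (`NA`) returns the sweep unchanged.
#'
#' @param sweep A [frequency_sweep()] or [modulus_spectrum()].
#' @param cutoff_hz Cutoff frequency from [detect_inertial_cutoff()].
#' @return The truncated object, same class as the input.
#' @export
truncate_at_cutoff <- function(sweep, cutoff_hz) {
  stopifnot(inherits(sweep, c("frequency_sweep", "modulus_spectrum")))
  if (is.na(cutoff_hz)) return(sweep)
  keep <- sweep$frequency_hz <= cutoff_hz
  if (!any(keep)) stop_input("cutoff removes every frequency point")
  for (field in c("frequency_hz", "storage_pa", "loss_pa")) {
    sweep[[field]] <- sweep[[field]][keep]
  }
  sweep
}

as_spectrum <- function(x, convention = "hz") {
  if (inherits(x, "modulus_spectrum")) return(x)
  modulus_spectrum(x$frequency_hz, x$storage_pa, x$loss_pa,
                   convention = convention)
}

#' Least-squares springpot fit to a modulus spectrum
#'
#' Fits the coefficient of consistence and fractional order to a (cutoff
#' truncated) spectrum by Levenberg-Marquardt least squares, using the
#' spectrum's angular-frequency convention. The default fits the storage and
#' loss channels jointly with equal per-point weights in log space; fitting
#' in log space stabilises the two-decade dynamic range of gel spectra, and
#' a storage-only mode is provided for materials whose loss modulus departs
#' from springpot phase behaviour (organ tissue does). `alpha` is constrained
#' to `[0, 1]`.
#'
#' @param spectrum A [modulus_spectrum()] or [frequency_sweep()] with at
#'   least 3 frequencies, truncated below the inertial cutoff.
#' @param channels `"joint"` (G' and G'') or `"storage_only"`.
#' @param log_space Fit residuals of log-moduli (default) instead of raw
#'   moduli; requires strictly positive observed moduli on the fitted
#'   channels.
#' @return A list of class `springpot_fit`: `params` ([springpot_params()]),
#'   `correlation` (Pearson correlation between observed and fitted moduli on
#'   the fitted channels, linear scale), `channels`, `log_space`,
#'   `convention`, `n`.
#' @examples
#' spec <- springpot_moduli(springpot_params(1500, 0.02), c(0.1, 0.3, 1))
#' fit_springpot(spec)
#' @export
fit_springpot <- function(spectrum, channels = c("joint", "storage_only"),
                          log_space = TRUE) {
  channels <- match.arg(channels)
  convention <- if (inherits(spectrum, "modulus_spectrum")) {
    spectrum$convention
  } else {
    "hz"
  }
  spectrum <- as_spectrum(spectrum, convention)
  f <- spectrum$frequency_hz
  if (length(f) < 3) stop_input("springpot fit needs at least 3 frequencies")
  omega <- angular_frequency(f, spectrum$convention)
  obs <- if (channels == "joint") {
    c(spectrum$storage_pa, spectrum$loss_pa)
  } else {
    spectrum$storage_pa
  }
  if (log_space && any(obs <= 0)) {
    stop_input("log-space fitting requires strictly positive moduli on the ",
               "fitted channels; use log_space = FALSE or storage_only")
  }

  model_fun <- function(p) {
    mag <- p[1] * omega^p[2]
    if (channels == "joint") {
      c(mag * cos(p[2] * pi / 2), mag * sin(p[2] * pi / 2))
    } else {
      mag * cos(p[2] * pi / 2)
    }
  }
  resid_fun <- function(p) {
    pred <- model_fun(p)
    if (log_space) log(pmax(pred, 1e-300)) - log(obs) else pred - obs
  }

  # initial values from the log-log slope of the storage channel
  pos <- spectrum$storage_pa > 0
  alpha0 <- if (sum(pos) >= 2) {
    min(max(stats::coef(stats::lm(log(spectrum$storage_pa[pos]) ~
                                    log(omega[pos])))[2], 0), 1)
  } else {
    0.1
  }
  k0 <- exp(mean(log(pmax(spectrum$storage_pa, 1e-300)) -
                   alpha0 * log(omega))) / max(cos(alpha0 * pi / 2), 1e-6)
  fit <- minpack.lm::nls.lm(par = c(k0, alpha0), fn = resid_fun,
                            lower = c(1e-12, 0), upper = c(Inf, 1),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  par <- fit$par
  fitted_vals <- model_fun(par)
  correlation <- if (stats::sd(obs) == 0 || stats::sd(fitted_vals) == 0) {
    1
  } else {
    stats::cor(obs, fitted_vals)
  }
  structure(list(params = springpot_params(par[1], min(max(par[2], 0), 1)),
                 correlation = correlation, channels = channels,
                 log_space = log_space, convention = spectrum$convention,
                 n = length(f)),
            class = "springpot_fit")
}

#' @export
print.springpot_fit <- function(x, ...) {
  cat(sprintf(
    "springpot fit (%s, %s): k_alpha = %.4g Pa.s^alpha, alpha = %.4g, r = %.4f\n",
    x$channels, x$convention, x$params$k_alpha, x$params$alpha,
    x$correlation))
  invisible(x)
}

#' Young modulus from a uniaxial compression record
#'
#' Ordinary least-squares slope of engineering stress versus engineering
#' strain over the initial linear portion of the record (default up to 2
#' percent axial strain). The slope is invariant to a constant stress offset.
#'
#' @param record A [uniaxial_record()].
#' @param max_strain Largest strain retained, dimensionless (default 0.02).
#' @return Young modulus in Pa.
#' @export
young_modulus <- function(record, max_strain = 0.02) {
  stopifnot(inherits(record, "uniaxial_record"))
  keep <- record$strain <= max_strain
  if (sum(keep) < 3) {
    stop_input("Young modulus needs at least 3 points at or below max_strain")
  }
  unname(stats::coef(stats::lm(record$stress_pa[keep] ~
                                 record$strain[keep]))[2])
}

#' Axial strain offset implied by the contact force
#'
#' The rheometer reports axial strain relative to the position at which the
#' contact force was established, so the true pre-strain is offset by the
#' strain already produced by that force: nominal contact stress
#' `sigma = F / (pi * (d/2)^2)` divided by the Young modulus. With the
#' protocol values (0.1 N on a 25 mm sample, E = 4.4 kPa) the offset is about
#' 4.6 percent.
#'
#' @param contact_force_n Contact force, N (non-negative).
#' @param diameter_mm Sample diameter, mm.
#' @param young_modulus_pa Young modulus, Pa; strictly positive.
#' @return A list with `offset_pct` (percent axial strain) and
#'   `nominal_stress_pa` (the intermediate contact stress).
#' @examples
#' axial_strain_offset(0.1, 25, 4400)
#' @export
axial_strain_offset <- function(contact_force_n, diameter_mm,
                                young_modulus_pa) {
  check_numeric(contact_force_n, "contact_force_n", nonneg = TRUE, len = 1)
  check_numeric(diameter_mm, "diameter_mm", positive = TRUE, len = 1)
  check_numeric(young_modulus_pa, "young_modulus_pa", positive = TRUE,
                len = 1)
  area_m2 <- pi * (diameter_mm / 2 / 1000)^2
  stress <- contact_force_n / area_m2
  list(offset_pct = 100 * stress / young_modulus_pa,
       nominal_stress_pa = stress)
}

#' Fit the linear pre-compression model
#'
#' Fits `k_alpha = k0 * (1 - b * axial_strain_pct)` by ordinary least squares
#' on the line `k_alpha = k0 - (k0 * b) * axial_strain_pct`, with the axial
#' strain in percent.
#'
#' @param axial_strain_pct Axial strains in percent; at least 3 distinct
#'   values.
#' @param k_alpha Fitted coefficients of consistence at each strain, same
#'   units throughout (Pa or kPa times s^alpha).
#' @param alpha Optional per-strain fractional orders; their median is stored
#'   as the model's central `alpha`.
#' @return A [precompression_model()].
#' @export
fit_precompression <- function(axial_strain_pct, k_alpha, alpha = NULL) {
  check_numeric(axial_strain_pct, "axial_strain_pct")
  check_numeric(k_alpha, "k_alpha", positive = TRUE,
                len = length(axial_strain_pct))
  if (length(unique(axial_strain_pct)) < 3) {
    stop_input("pre-compression fit needs at least 3 distinct axial strains")
  }
  co <- stats::coef(stats::lm(k_alpha ~ axial_strain_pct))
  k0 <- unname(co[1])
  slope <- unname(co[2])
  if (k0 <= 0) stop_input("fitted k0 is non-positive; data are not springpot-like")
  precompression_model(k0 = k0, b = -slope / k0,
                       alpha = if (is.null(alpha)) NA_real_
                               else stats::median(alpha),
                       strain_range_pct = range(axial_strain_pct))
}

#' Fit the concentration power law
#'
#' Least-squares fit of `log G'` versus `log c` for the storage modulus as a
#' function of gel concentration; the amplitude is the storage modulus at 1
#' percent concentration.
#'
#' @param concentration_pct Concentrations in percent by mass; at least 3
#'   distinct positive values.
#' @param storage_kpa Storage moduli in kPa, strictly positive.
#' @return A [concentration_power_law()].
#' @export
fit_concentration_power_law <- function(concentration_pct, storage_kpa) {
  check_numeric(concentration_pct, "concentration_pct", positive = TRUE)
  check_numeric(storage_kpa, "storage_kpa", positive = TRUE,
                len = length(concentration_pct))
  if (length(unique(concentration_pct)) < 3) {
    stop_input("power-law fit needs at least 3 distinct concentrations")
  }
  co <- stats::coef(stats::lm(log(storage_kpa) ~ log(concentration_pct)))
  concentration_power_law(amplitude_kpa = exp(unname(co[1])),
                          exponent = unname(co[2]))
}
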