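# Synthetic rheometer records with the statistical structure the analysis
# assumes: springpot spectra with weak power-law frequency dependence,
# LVE-plateau-then-softening amplitude sweeps, inertial high-frequency
# collapse, linear low-strain compression, a linear decrease of the
# coefficient of consistence with axial pre-strain, and relaxation traces
# that are near-flat for gels and decay over seconds for organs.

#' Multiplicative noise specification
#'
#' Noise on generated moduli is lognormal (multiplicative and strictly
#' positive), so log-space fitting never receives non-positive values.
#'
#' @param multiplicative_sd Standard deviation of the log noise factor
#'   (approximately the relative sd for small values); non-negative.
#' @param seed Optional integer seed; generation is bit-reproducible under a
#'   fixed seed and grid.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(multiplicative_sd = 0.02, seed = NULL) {
  check_numeric(multiplicative_sd, "multiplicative_sd", nonneg = TRUE,
                len = 1)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(multiplicative_sd = multiplicative_sd, seed = seed),
            class = "noise_spec")
}

noise_factors <- function(n, noise) {
  if (is.null(noise)) return(rep(1, n))
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$multiplicative_sd == 0) return(rep(1, n))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  exp(stats::rnorm(n, 0, noise$multiplicative_sd))
}

default_meta <- function(material = "agarose", concentration_pct = 0.3,
                         sample_id = NULL) {
  if (material != "agarose") concentration_pct <- NULL
  sample_meta(sample_id = sample_id %||%
                paste0(material,
                       if (!is.null(concentration_pct)) {
                         paste0("-", concentration_pct)
                       } else ""),
              material = material, concentration_pct = concentration_pct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic frequency sweep
#'
#' Springpot moduli multiplied by lognormal noise; above an optional inertial
#' cutoff `f_c` a monotone collapse factor `pmax(1 - ((f - f_c)/f_c)^2, 0)`
#' is applied to both channels to emulate the inertial drop seen in measured
#' spectra (an empirical shape, not an inertia model).
#'
#' @param params A [springpot_params()].
#' @param frequency_hz Strictly increasing positive grid, Hz.
#' @param noise A [noise_spec()] or `NULL` for none.
#' @param inertial_cutoff_hz Cutoff frequency, or `NA` for no inertial drop;
#'   must not lie below the first grid point.
#' @param convention Angular-frequency convention for the springpot moduli.
#' @param meta A [sample_meta()]; a default agarose sample when omitted.
#' @param axial_strain_pct Total axial pre-strain recorded on the sweep.
#' @param shear_strain_pct Fixed shear strain amplitude, percent.
#' @return A [frequency_sweep()].
#' @export
gen_frequency_sweep <- function(params, frequency_hz, noise = noise_spec(),
                                inertial_cutoff_hz = NA,
                                convention = c("hz", "rad_s"), meta = NULL,
                                axial_strain_pct = 4.6,
                                shear_strain_pct = 0.1) {
  convention <- match_convention(convention)
  spec <- springpot_moduli(params, frequency_hz, convention)
  if (!is.na(inertial_cutoff_hz)) {
    if (inertial_cutoff_hz < frequency_hz[1]) {
      stop_input("inertial cutoff lies below the first grid frequency")
    }
    fc <- inertial_cutoff_hz
    collapse <- ifelse(frequency_hz > fc,
                       pmax(1 - ((frequency_hz - fc) / fc)^2, 0), 1)
    spec$storage_pa <- spec$storage_pa * collapse
    spec$loss_pa <- spec$loss_pa * collapse
  }
  fac <- noise_factors(2 * length(frequency_hz), noise)
  n <- length(frequency_hz)
  frequency_sweep(meta %||% default_meta(),
                  frequency_hz = frequency_hz,
                  storage_pa = spec$storage_pa * fac[seq_len(n)],
                  loss_pa = spec$loss_pa * fac[n + seq_len(n)],
                  shear_strain_pct = shear_strain_pct,
                  axial_strain_pct = axial_strain_pct)
}

#' Generate a synthetic amplitude (strain) sweep
#'
#' A plateau-then-soften storage modulus `plateau / (1 + (g/g_c)^m)` and a
#' plateau-then-bump loss modulus `plateau_loss * (1 + gain * (g/g_c)^2 /
#' (1 + (g/g_c)^3))`, where `g` is the strain amplitude and `g_c` the
#' critical strain. Both are smooth two-parameter conveniences reproducing
#' the observed curve shapes (LVE plateau, G' softening, G'' rise), not a
#' physical softening model. At `g = g_c` the noiseless storage modulus is
#' exactly half the plateau.
#'
#' @param plateau_storage_pa,plateau_loss_pa LVE plateau moduli, Pa.
#' @param critical_strain_pct Critical strain `g_c`, percent; must lie within
#'   the grid span.
#' @param softening_exponent Hill exponent `m` of the storage softening.
#' @param loss_peak_gain Relative height of the loss bump.
#' @param strain_pct Strictly increasing strain grid, percent.
#' @param noise A [noise_spec()] or `NULL`.
#' @param meta A [sample_meta()].
#' @param frequency_hz Fixed oscillation frequency, Hz.
#' @return A [strain_sweep()].
#' @export
gen_strain_sweep <- function(plateau_storage_pa, plateau_loss_pa,
                             critical_strain_pct, softening_exponent = 2,
                             loss_peak_gain = 1,
                             strain_pct = 10^seq(-2, 1, length.out = 25),
                             noise = noise_spec(), meta = NULL,
                             frequency_hz = 1) {
  check_numeric(plateau_storage_pa, "plateau_storage_pa", positive = TRUE,
                len = 1)
  check_numeric(plateau_loss_pa, "plateau_loss_pa", positive = TRUE, len = 1)
  check_numeric(critical_strain_pct, "critical_strain_pct", positive = TRUE,
                len = 1)
  x <- strain_pct / critical_strain_pct
  storage <- plateau_storage_pa / (1 + x^softening_exponent)
  loss <- plateau_loss_pa * (1 + loss_peak_gain * x^2 / (1 + x^3))
  n <- length(strain_pct)
  fac <- noise_factors(2 * n, noise)
  strain_sweep(meta %||% default_meta(), strain_pct = strain_pct,
               storage_pa = storage * fac[seq_len(n)],
               loss_pa = loss * fac[n + seq_len(n)],
               frequency_hz = frequency_hz)
}

#' Generate a synthetic uniaxial compression record
#'
#' Linear engineering stress-strain behaviour `sigma = E * epsilon` with
#' multiplicative noise on the stress, matching the low-strain (to 2 percent)
#' linearity of gel compression tests.
#'
#' @param young_modulus_pa Young modulus E, Pa.
#' @param max_strain Largest engineering strain, dimensionless.
#' @param grid_points Number of strain points (including zero); at least 2.
#' @param noise A [noise_spec()] or `NULL`.
#' @param meta A [sample_meta()].
#' @return A [uniaxial_record()].
#' @export
gen_uniaxial <- function(young_modulus_pa, max_strain = 0.02,
                         grid_points = 11, noise = noise_spec(),
                         meta = NULL) {
  check_numeric(young_modulus_pa, "young_modulus_pa", positive = TRUE,
                len = 1)
  check_numeric(max_strain, "max_strain", positive = TRUE, len = 1)
  if (grid_points < 2) stop_input("'grid_points' must be at least 2")
  strain <- seq(0, max_strain, length.out = grid_points)
  stress <- young_modulus_pa * strain * noise_factors(grid_points, noise)
  uniaxial_record(meta %||% default_meta(), strain = strain,
                  stress_pa = stress)
}

#' Generate a synthetic relaxation trace
#'
#' The springpot power-law relaxation modulus multiplied by
#' `(1 - extra_decay_fraction) + extra_decay_fraction * exp(-t / tau)` and by
#' lognormal noise. With `extra_decay_fraction = 0` the trace is a pure
#' springpot (gel-like, near-flat for small alpha); a non-zero fraction adds
#' the seconds-scale exponential decay organs show, purely to give
#' matching and comparison code realistic contrast.
#'
#' @param params A [springpot_params()] with `alpha < 1`.
#' @param time_s Strictly increasing positive time grid, s.
#' @param noise A [noise_spec()] or `NULL`.
#' @param extra_decay_fraction Fraction of the modulus that relaxes away, in
#'   `[0, 1]`.
#' @param extra_decay_tau_s Decay time constant, s; required positive when
#'   the fraction is non-zero.
#' @param step_strain Step strain amplitude recorded on the trace.
#' @param meta A [sample_meta()].
#' @return A [relaxation_trace()].
#' @export
gen_relaxation <- function(params, time_s, noise = noise_spec(),
                           extra_decay_fraction = 0, extra_decay_tau_s = NA,
                           step_strain = 0.001, meta = NULL) {
  check_numeric(extra_decay_fraction, "extra_decay_fraction", nonneg = TRUE,
                len = 1)
  if (extra_decay_fraction > 1) {
    stop_input("'extra_decay_fraction' must lie in [0, 1]")
  }
  base <- springpot_relaxation(params, time_s, step_strain = step_strain)
  g <- base$relaxation_modulus_pa
  if (extra_decay_fraction > 0) {
    if (is.na(extra_decay_tau_s) || extra_decay_tau_s <= 0) {
      stop_input("a positive 'extra_decay_tau_s' is required when ",
                 "'extra_decay_fraction' > 0")
    }
    g <- g * ((1 - extra_decay_fraction) +
                extra_decay_fraction * exp(-time_s / extra_decay_tau_s))
  }
  relaxation_trace(time_s, g * noise_factors(length(time_s), noise),
                   step_strain = step_strain, ramp_s = 1,
                   meta = meta %||% default_meta())
}

#' Study configuration for the synthetic dataset
#'
#' Defaults mirror the rheometry protocols the analysis targets: amplitude
#' sweeps 0.01-10 percent at 1 Hz; frequency sweeps from 0.1 Hz at 0.1
#' percent shear strain; 0.1 N contact force on 25 mm samples; axial
#' pre-strains in 2 percent steps above the contact offset; relaxation read
#' over 0.1-10 s. Gel stiffness follows the concentration power law
#' `G' = 10.8 * c^2.3` kPa with fractional order 0.019; the pre-compression
#' slopes and inertial cutoffs are per-concentration; organs are
#' parameterised by their storage modulus at 0.1 Hz, a larger fractional
#' order, and an extra exponential relaxation component.
#'
#' @param concentrations Gel concentrations, percent by mass.
#' @param power_law A [concentration_power_law()] giving the plateau storage
#'   modulus (kPa) at 1 Hz as a function of concentration.
#' @param alpha_agarose Fractional order of the gels.
#' @param precompression_b Named vector (by concentration) of fractional
#'   decreases of `k_alpha` per percent axial strain.
#' @param inertial_cutoff_hz Named vector (by concentration) of cutoff
#'   frequencies, Hz.
#' @param organ_params Named list: organ -> list(`storage_kpa_0p1hz`,
#'   `alpha`, `tau_s`, `decay_fraction`, `cutoff_hz`).
#' @param young_modulus_kpa Gel Young modulus used for the contact offset,
#'   kPa.
#' @param strain_grid_pct,frequency_grid_hz,time_grid_s Measurement grids.
#' @param extra_axial_strain_pct Machine-reported axial strains (relative to
#'   contact) at which frequency sweeps are repeated, percent.
#' @param critical_strain_pct Named vector (by concentration) of amplitude
#'   sweep critical strains, percent.
#' @param contact_force_n,diameter_mm,thickness_mm Geometry and contact
#'   force.
#' @param noise_sd Multiplicative noise sd.
#' @param seed Integer seed for the whole study.
#' @param convention Angular-frequency convention.
#' @return An object of class `study_config`.
#' @export
study_config <- function(concentrations = c(0.25, 0.3, 0.4),
                         power_law = concentration_power_law(10.8, 2.3),
                         alpha_agarose = 0.019,
                         precompression_b = c("0.25" = 0.006, "0.3" = 0.017,
                                              "0.4" = 0.021),
                         inertial_cutoff_hz = c("0.25" = 0.8, "0.3" = 1.2,
                                                "0.4" = 1.2),
                         organ_params = list(
                           heart = list(storage_kpa_0p1hz = 1.4, alpha = 0.1,
                                        tau_s = 2, decay_fraction = 0.3,
                                        cutoff_hz = 9.5),
                           kidney = list(storage_kpa_0p1hz = 0.6, alpha = 0.1,
                                         tau_s = 2, decay_fraction = 0.3,
                                         cutoff_hz = 9.5),
                           liver = list(storage_kpa_0p1hz = 0.2, alpha = 0.1,
                                        tau_s = 2, decay_fraction = 0.3,
                                        cutoff_hz = 4.2)),
                         young_modulus_kpa = 4.4,
                         strain_grid_pct = 10^seq(-2, 1, length.out = 25),
                         frequency_grid_hz = unique(sort(c(
                           10^seq(-1, 0.5, length.out = 14), 0.8, 1.2))),
                         time_grid_s = 10^seq(-1, 1, length.out = 41),
                         extra_axial_strain_pct = c(0, 2, 4, 6, 8, 10),
                         critical_strain_pct = c("0.25" = 3, "0.3" = 2,
                                                 "0.4" = 1.5),
                         contact_force_n = 0.1, diameter_mm = 25,
                         thickness_mm = 5.5, noise_sd = 0.02, seed = 1,
                         convention = c("hz", "rad_s")) {
  convention <- match_convention(convention)
  check_numeric(concentrations, "concentrations", positive = TRUE)
  stopifnot(inherits(power_law, "concentration_power_law"))
  check_numeric(strain_grid_pct, "strain_grid_pct", positive = TRUE,
                increasing = TRUE)
  check_numeric(frequency_grid_hz, "frequency_grid_hz", positive = TRUE,
                increasing = TRUE)
  check_numeric(time_grid_s, "time_grid_s", positive = TRUE,
                increasing = TRUE)
  structure(list(concentrations = concentrations, power_law = power_law,
                 alpha_agarose = alpha_agarose,
                 precompression_b = precompression_b,
                 inertial_cutoff_hz = inertial_cutoff_hz,
                 organ_params = organ_params,
                 young_modulus_kpa = young_modulus_kpa,
                 strain_grid_pct = strain_grid_pct,
                 frequency_grid_hz = frequency_grid_hz,
                 time_grid_s = time_grid_s,
                 extra_axial_strain_pct = extra_axial_strain_pct,
                 critical_strain_pct = critical_strain_pct,
                 contact_force_n = contact_force_n, diameter_mm = diameter_mm,
                 thickness_mm = thickness_mm, noise_sd = noise_sd,
                 seed = as.integer(seed), convention = convention),
            class = "study_config")
}

conc_lookup <- function(map, conc, default) {
  key <- as.character(conc)
  if (!is.null(names(map)) && key %in% names(map)) {
    unname(map[[key]])
  } else {
    default
  }
}

#' Generate a full synthetic study
#'
#' Produces every record kind for every configured gel concentration and
#' organ. For each concentration the contact-force coefficient of consistence
#' is set from the power law (plateau G' at 1 Hz approximately equals
#' `k_alpha` for small alpha); frequency sweeps are generated at each
#' configured axial strain with `k_alpha` scaled by the linear
#' pre-compression law `k0 * (1 - b * strain_pct)` anchored so that the
#' contact-offset strain reproduces the power-law value. Organs use their
#' configured storage modulus at 0.1 Hz and relaxation parameters. Record
#' seeds are derived deterministically from the study seed.
#'
#' @param config A [study_config()].
#' @return A list of class `study_data`: `strain_sweeps`,
#'   `frequency_sweeps` (nested by sample then axial strain), `uniaxial`,
#'   `relaxation`, `truth` (the generating parameters), `config`.
#' @export
gen_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  offset <- axial_strain_offset(config$contact_force_n, config$diameter_mm,
                                config$young_modulus_kpa * 1000)$offset_pct
  seed_counter <- config$seed
  next_noise <- function() {
    seed_counter <<- seed_counter + 1L
    noise_spec(config$noise_sd, seed = seed_counter)
  }
  alpha <- config$alpha_agarose
  phase <- cos(alpha * pi / 2)
  strain_sweeps <- list()
  frequency_sweeps <- list()
  uniaxial <- list()
  relaxation <- list()
  truth <- list(offset_pct = offset, agarose = list(), organs = list())

  for (conc in config$concentrations) {
    key <- as.character(conc)
    meta <- default_meta("agarose", conc)
    g_ref_pa <- predict_power_law(config$power_law, conc) * 1000
    k_ref <- g_ref_pa / (phase *
                           angular_frequency(1, config$convention)^alpha)
    b <- conc_lookup(config$precompression_b, conc, 0.02)
    k0 <- k_ref / (1 - b * offset)
    cutoff <- conc_lookup(config$inertial_cutoff_hz, conc, NA_real_)
    gc_pct <- conc_lookup(config$critical_strain_pct, conc, 2)
    truth$agarose[[key]] <- list(k_alpha_contact = k_ref, alpha = alpha,
                                 k0 = k0, b = b, cutoff_hz = cutoff,
                                 plateau_storage_pa = g_ref_pa)

    strain_sweeps[[key]] <- gen_strain_sweep(
      plateau_storage_pa = g_ref_pa,
      plateau_loss_pa = k_ref * sin(alpha * pi / 2) *
        angular_frequency(1, config$convention)^alpha,
      critical_strain_pct = gc_pct, strain_pct = config$strain_grid_pct,
      noise = next_noise(), meta = meta)

    sweeps <- list()
    for (extra in config$extra_axial_strain_pct) {
      total <- offset + extra
      params <- springpot_params(k0 * (1 - b * total), alpha)
      sweeps[[as.character(extra)]] <- gen_frequency_sweep(
        params, config$frequency_grid_hz, noise = next_noise(),
        inertial_cutoff_hz = cutoff, convention = config$convention,
        meta = meta, axial_strain_pct = total)
    }
    frequency_sweeps[[key]] <- sweeps

    uniaxial[[key]] <- gen_uniaxial(config$young_modulus_kpa * 1000,
                                    noise = next_noise(), meta = meta)
    relaxation[[key]] <- gen_relaxation(
      springpot_params(k_ref, alpha), config$time_grid_s,
      noise = next_noise(), meta = meta)
  }

  for (organ in names(config$organ_params)) {
    p <- config$organ_params[[organ]]
    meta <- default_meta(organ)
    omega_ref <- angular_frequency(0.1, config$convention)
    k_organ <- p$storage_kpa_0p1hz * 1000 /
      (omega_ref^p$alpha * cos(p$alpha * pi / 2))
    params <- springpot_params(k_organ, p$alpha)
    truth$organs[[organ]] <- list(k_alpha = k_organ, alpha = p$alpha,
                                  storage_pa_0p1hz = p$storage_kpa_0p1hz * 1000)
    frequency_sweeps[[organ]] <- list(
      "0" = gen_frequency_sweep(params, config$frequency_grid_hz,
                                noise = next_noise(),
                                inertial_cutoff_hz = p$cutoff_hz,
                                convention = config$convention, meta = meta,
                                axial_strain_pct = 0))
    relaxation[[organ]] <- gen_relaxation(
      params, config$time_grid_s, noise = next_noise(),
      extra_decay_fraction = p$decay_fraction,
      extra_decay_tau_s = p$tau_s, meta = meta)
  }

  structure(list(strain_sweeps = strain_sweeps,
                 frequency_sweeps = frequency_sweeps, uniaxial = uniaxial,
                 relaxation = relaxation, truth = truth, config = config),
            class = "study_data")
}
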