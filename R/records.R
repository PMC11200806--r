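# Record classes shared across the package. All are plain lists with a class
# attribute and validated fields; units are SI on the inside (Pa, Hz, s, N)
# with strains carried in percent where the rheometry protocol uses percent.

stop_input <- function(...) stop(..., call. = FALSE)

check_numeric <- function(x, name, positive = FALSE, nonneg = FALSE,
                          increasing = FALSE, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_input(sprintf("'%s' must be numeric with no missing values", name))
  }
  if (positive && any(x <= 0)) {
    stop_input(sprintf("'%s' must be strictly positive", name))
  }
  if (nonneg && any(x < 0)) {
    stop_input(sprintf("'%s' must be non-negative", name))
  }
  if (increasing && is.unsorted(x, strictly = TRUE)) {
    stop_input(sprintf("'%s' must be strictly increasing", name))
  }
  if (!is.null(len) && length(x) != len) {
    stop_input(sprintf("'%s' must have length %d", name, len))
  }
  invisible(x)
}

match_convention <- function(convention) {
  match.arg(convention, c("hz", "rad_s"))
}

#' Angular frequency under a stated convention
#'
#' The springpot moduli expressions use an angular frequency `omega`. Rheometer
#' software reports cyclic frequency in Hz, and fitted parameter tables in this
#' field are only self-consistent under one interpretation of `omega`, so the
#' interpretation is an explicit argument everywhere rather than an assumption:
#' `"hz"` takes `omega` numerically equal to the cyclic frequency, `"rad_s"`
#' takes `omega = 2 * pi * f`.
#'
#' @param frequency_hz Cyclic frequency in Hz.
#' @param convention `"hz"` or `"rad_s"`.
#' @return Numeric vector of `omega` values.
#' @export
angular_frequency <- function(frequency_hz, convention = c("hz", "rad_s")) {
  convention <- match_convention(convention)
  if (convention == "hz") frequency_hz else 2 * pi * frequency_hz
}

#' Springpot parameters
#'
#' The springpot is a fractional-order viscoelastic element whose stress is the
#' alpha-th fractional derivative of strain scaled by the coefficient of
#' consistence `k_alpha` (units Pa s^alpha). It interpolates between a spring
#' (`alpha = 0`, `k_alpha` the shear modulus) and a dashpot (`alpha = 1`,
#' `k_alpha` the viscosity).
#'
#' @param k_alpha Coefficient of consistence, Pa s^alpha; strictly positive.
#' @param alpha Fractional order in `[0, 1]`.
#' @return An object of class `springpot_params`.
#' @export
springpot_params <- function(k_alpha, alpha) {
  check_numeric(k_alpha, "k_alpha", positive = TRUE, len = 1)
  check_numeric(alpha, "alpha", len = 1)
  if (alpha < 0 || alpha > 1) {
    stop_input("'alpha' must lie in [0, 1]")
  }
  structure(list(k_alpha = k_alpha, alpha = alpha), class = "springpot_params")
}

#' @export
print.springpot_params <- function(x, ...) {
  cat(sprintf("springpot: k_alpha = %g Pa.s^alpha, alpha = %.4g\n",
              x$k_alpha, x$alpha))
  invisible(x)
}

#' Classical viscoelastic element parameters
#'
#' Parameters for the spring, dashpot, Kelvin-Voigt (parallel) and Maxwell
#' (series) comparator models.
#'
#' @param kind One of `"spring"`, `"dashpot"`, `"kelvin_voigt"`, `"maxwell"`.
#' @param shear_modulus Shear modulus G in Pa (not used by a pure dashpot).
#' @param viscosity Viscosity eta in Pa s (not used by a pure spring).
#' @return An object of class `classical_params`.
#' @export
classical_params <- function(kind = c("spring", "dashpot", "kelvin_voigt",
                                      "maxwell"),
                             shear_modulus = NULL, viscosity = NULL) {
  kind <- match.arg(kind)
  needs_g <- kind != "dashpot"
  needs_eta <- kind != "spring"
  if (needs_g) {
    if (is.null(shear_modulus)) {
      stop_input(sprintf("'shear_modulus' is required for kind '%s'", kind))
    }
    check_numeric(shear_modulus, "shear_modulus", positive = TRUE, len = 1)
  }
  if (needs_eta) {
    if (is.null(viscosity)) {
      stop_input(sprintf("'viscosity' is required for kind '%s'", kind))
    }
    # eta = 0 is allowed only for Kelvin-Voigt, where it degenerates to a spring
    if (kind == "kelvin_voigt") {
      check_numeric(viscosity, "viscosity", nonneg = TRUE, len = 1)
    } else {
      check_numeric(viscosity, "viscosity", positive = TRUE, len = 1)
    }
  }
  structure(list(kind = kind, shear_modulus = shear_modulus,
                 viscosity = viscosity),
            class = "classical_params")
}

#' Storage/loss modulus spectrum
#'
#' Frequency-indexed storage and loss moduli, the unit of springpot fitting.
#' The spectrum records which angular-frequency convention produced (or should
#' be used to fit) it.
#'
#' @param frequency_hz Strictly increasing positive cyclic frequencies, Hz.
#' @param storage_pa Storage modulus G' in Pa, non-negative.
#' @param loss_pa Loss modulus G'' in Pa, non-negative.
#' @param convention Angular-frequency convention, `"hz"` or `"rad_s"`.
#' @return An object of class `modulus_spectrum`.
#' @export
modulus_spectrum <- function(frequency_hz, storage_pa, loss_pa,
                             convention = c("hz", "rad_s")) {
  convention <- match_convention(convention)
  check_numeric(frequency_hz, "frequency_hz", positive = TRUE,
                increasing = TRUE)
  n <- length(frequency_hz)
  check_numeric(storage_pa, "storage_pa", nonneg = TRUE, len = n)
  check_numeric(loss_pa, "loss_pa", nonneg = TRUE, len = n)
  structure(list(frequency_hz = frequency_hz, storage_pa = storage_pa,
                 loss_pa = loss_pa, convention = convention),
            class = "modulus_spectrum")
}

#' @export
print.modulus_spectrum <- function(x, ...) {
  cat(sprintf("modulus spectrum: %d frequencies in [%g, %g] Hz (%s convention)\n",
              length(x$frequency_hz), min(x$frequency_hz),
              max(x$frequency_hz), x$convention))
  invisible(x)
}

#' Relaxation trace
#'
#' Relaxation modulus G(t) following a (nominal) step shear strain. The step
#' amplitude and the finite ramp duration over which the step was applied are
#' part of the protocol and stored with the trace.
#'
#' @param time_s Strictly increasing positive times, s.
#' @param relaxation_modulus_pa Relaxation modulus, Pa, non-negative.
#' @param step_strain Dimensionless step strain amplitude (0.001 for the
#'   0.1 percent protocol), strictly positive.
#' @param ramp_s Duration over which the nominal step is applied, s.
#' @param meta Optional [sample_meta()].
#' @return An object of class `relaxation_trace`.
#' @export
relaxation_trace <- function(time_s, relaxation_modulus_pa,
                             step_strain = 0.001, ramp_s = 1, meta = NULL) {
  check_numeric(time_s, "time_s", positive = TRUE, increasing = TRUE)
  check_numeric(relaxation_modulus_pa, "relaxation_modulus_pa", nonneg = TRUE,
                len = length(time_s))
  check_numeric(step_strain, "step_strain", positive = TRUE, len = 1)
  check_numeric(ramp_s, "ramp_s", nonneg = TRUE, len = 1)
  structure(list(time_s = time_s,
                 relaxation_modulus_pa = relaxation_modulus_pa,
                 step_strain = step_strain, ramp_s = ramp_s, meta = meta),
            class = "relaxation_trace")
}

#' Sample metadata
#'
#' Identity and geometry of a tested sample: agarose gels carry a
#' concentration (percent by mass); porcine organ samples do not.
#'
#' @param sample_id Character identifier.
#' @param material One of `"agarose"`, `"heart"`, `"kidney"`, `"liver"`.
#' @param concentration_pct Agarose concentration, percent by mass; required
#'   iff `material == "agarose"`.
#' @param diameter_mm Sample diameter, mm (protocol default 25).
#' @param thickness_mm Sample thickness, mm.
#' @param contact_force_n Axial contact force before shear testing, N
#'   (protocol default 0.1).
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, material = c("agarose", "heart", "kidney",
                                                "liver"),
                        concentration_pct = NULL, diameter_mm = 25,
                        thickness_mm = 5.5, contact_force_n = 0.1) {
  material <- match.arg(material)
  if (material == "agarose") {
    if (is.null(concentration_pct)) {
      stop_input("agarose samples require 'concentration_pct'")
    }
    check_numeric(concentration_pct, "concentration_pct", positive = TRUE,
                  len = 1)
  } else if (!is.null(concentration_pct)) {
    stop_input("'concentration_pct' is only meaningful for agarose")
  }
  check_numeric(diameter_mm, "diameter_mm", positive = TRUE, len = 1)
  check_numeric(thickness_mm, "thickness_mm", positive = TRUE, len = 1)
  check_numeric(contact_force_n, "contact_force_n", nonneg = TRUE, len = 1)
  structure(list(sample_id = as.character(sample_id), material = material,
                 concentration_pct = concentration_pct,
                 diameter_mm = diameter_mm, thickness_mm = thickness_mm,
                 contact_force_n = contact_force_n),
            class = "sample_meta")
}

#' Amplitude (strain) sweep record
#'
#' Moduli measured while the shear strain amplitude increases at a fixed
#' oscillation frequency (protocol: 0.01 to 10 percent at 1 Hz).
#'
#' @param meta A [sample_meta()].
#' @param strain_pct Strictly increasing strain amplitudes in percent,
#'   within (0, 100).
#' @param storage_pa,loss_pa Moduli in Pa.
#' @param frequency_hz Fixed oscillation frequency, Hz (default 1).
#' @return An object of class `strain_sweep`.
#' @export
strain_sweep <- function(meta, strain_pct, storage_pa, loss_pa,
                         frequency_hz = 1) {
  stopifnot(inherits(meta, "sample_meta"))
  check_numeric(strain_pct, "strain_pct", positive = TRUE, increasing = TRUE)
  if (any(strain_pct >= 100)) stop_input("'strain_pct' must be below 100")
  n <- length(strain_pct)
  check_numeric(storage_pa, "storage_pa", nonneg = TRUE, len = n)
  check_numeric(loss_pa, "loss_pa", nonneg = TRUE, len = n)
  check_numeric(frequency_hz, "frequency_hz", positive = TRUE, len = 1)
  structure(list(meta = meta, frequency_hz = frequency_hz,
                 strain_pct = strain_pct, storage_pa = storage_pa,
                 loss_pa = loss_pa),
            class = "strain_sweep")
}

#' Frequency sweep record
#'
#' Moduli measured while frequency increases at a fixed shear strain
#' (protocol: from 0.1 Hz at 0.1 percent strain), at a stated total axial
#' pre-strain (contact-force offset included).
#'
#' @param meta A [sample_meta()].
#' @param frequency_hz Strictly increasing positive frequencies, Hz.
#' @param storage_pa,loss_pa Moduli in Pa.
#' @param shear_strain_pct Fixed shear strain amplitude, percent (default 0.1).
#' @param axial_strain_pct Total axial pre-strain, percent (offset-corrected).
#' @return An object of class `frequency_sweep`.
#' @export
frequency_sweep <- function(meta, frequency_hz, storage_pa, loss_pa,
                            shear_strain_pct = 0.1, axial_strain_pct = 0) {
  stopifnot(inherits(meta, "sample_meta"))
  check_numeric(frequency_hz, "frequency_hz", positive = TRUE,
                increasing = TRUE)
  n <- length(frequency_hz)
  check_numeric(storage_pa, "storage_pa", nonneg = TRUE, len = n)
  check_numeric(loss_pa, "loss_pa", nonneg = TRUE, len = n)
  check_numeric(shear_strain_pct, "shear_strain_pct", positive = TRUE, len = 1)
  check_numeric(axial_strain_pct, "axial_strain_pct", nonneg = TRUE, len = 1)
  structure(list(meta = meta, shear_strain_pct = shear_strain_pct,
                 axial_strain_pct = axial_strain_pct,
                 frequency_hz = frequency_hz, storage_pa = storage_pa,
                 loss_pa = loss_pa),
            class = "frequency_sweep")
}

#' Uniaxial compression record
#'
#' Engineering stress-strain pairs from a uniaxial compression test
#' (stress = F/A, strain = dL/L relative to the contact point).
#'
#' @param meta A [sample_meta()].
#' @param strain Dimensionless engineering strain, increasing from 0.
#' @param stress_pa Engineering stress, Pa, non-negative.
#' @return An object of class `uniaxial_record`.
#' @export
uniaxial_record <- function(meta, strain, stress_pa) {
  stopifnot(inherits(meta, "sample_meta"))
  check_numeric(strain, "strain", nonneg = TRUE, increasing = TRUE)
  if (length(strain) < 2) stop_input("'strain' needs at least 2 points")
  check_numeric(stress_pa, "stress_pa", nonneg = TRUE, len = length(strain))
  structure(list(meta = meta, strain = strain, stress_pa = stress_pa),
            class = "uniaxial_record")
}

#' Linear pre-compression model for the coefficient of consistence
#'
#' Axial pre-compression lowers the springpot coefficient of consistence
#' approximately linearly: `k_alpha = k0 * (1 - b * axial_strain_pct)`, with
#' the axial strain expressed in percent.
#'
#' @param k0 Coefficient of consistence extrapolated to zero axial strain,
#'   Pa s^alpha; strictly positive.
#' @param b Fractional decrease per percent axial strain.
#' @param alpha Central fractional order across the per-strain fits.
#' @param strain_range_pct Optional range (percent) over which the model was
#'   fitted; used to check positivity of the prediction.
#' @return An object of class `precompression_model`.
#' @export
precompression_model <- function(k0, b, alpha = NA_real_,
                                 strain_range_pct = NULL) {
  check_numeric(k0, "k0", positive = TRUE, len = 1)
  check_numeric(b, "b", len = 1)
  if (!is.null(strain_range_pct)) {
    pred <- k0 * (1 - b * strain_range_pct)
    if (any(pred <= 0)) {
      warning("pre-compression model predicts non-positive k_alpha within ",
              "the fitted strain range", call. = FALSE)
    }
  }
  structure(list(k0 = k0, b = b, alpha = alpha,
                 strain_range_pct = strain_range_pct),
            class = "precompression_model")
}

#' Evaluate a pre-compression model
#'
#' @param model A [precompression_model()].
#' @param axial_strain_pct Axial strain values in percent.
#' @return Predicted `k_alpha` in the units of `k0`.
#' @export
predict_k_alpha <- function(model, axial_strain_pct) {
  stopifnot(inherits(model, "precompression_model"))
  model$k0 * (1 - model$b * axial_strain_pct)
}

#' Concentration power law for the storage modulus
#'
#' `G' = A * c^b` with `c` the gel concentration in percent by mass and `A`
#' the storage modulus at 1 percent concentration.
#'
#' @param amplitude_kpa `A`, kPa; strictly positive.
#' @param exponent `b`, dimensionless.
#' @return An object of class `concentration_power_law`.
#' @export
concentration_power_law <- function(amplitude_kpa, exponent) {
  check_numeric(amplitude_kpa, "amplitude_kpa", positive = TRUE, len = 1)
  check_numeric(exponent, "exponent", len = 1)
  structure(list(amplitude_kpa = amplitude_kpa, exponent = exponent),
            class = "concentration_power_law")
}

#' Evaluate a concentration power law
#'
#' @param law A [concentration_power_law()].
#' @param concentration_pct Concentrations in percent by mass.
#' @return Predicted storage modulus in kPa.
#' @export
predict_power_law <- function(law, concentration_pct) {
  stopifnot(inherits(law, "concentration_power_law"))
  check_numeric(concentration_pct, "concentration_pct", positive = TRUE)
  law$amplitude_kpa * concentration_pct^law$exponent
}
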