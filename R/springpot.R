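# Closed-form springpot and classical viscoelastic responses, plus a
# Grunwald-Letnikov discretisation of the fractional derivative used as an
# independent time-domain reference.

#' Springpot storage and loss moduli
#'
#' Under oscillatory shear at angular frequency omega, a springpot with
#' coefficient of consistence `k_alpha` and fractional order `alpha` has
#' storage modulus `k_alpha * omega^alpha * cos(alpha*pi/2)` and loss modulus
#' `k_alpha * omega^alpha * sin(alpha*pi/2)`. The interpretation of omega
#' (cyclic Hz vs rad/s) is controlled by `convention` and recorded in the
#' returned spectrum; see [angular_frequency()].
#'
#' @param params A [springpot_params()].
#' @param frequency_hz Strictly increasing positive cyclic frequencies, Hz.
#' @param convention `"hz"` (default) or `"rad_s"`.
#' @return A [modulus_spectrum()].
#' @examples
#' sp <- springpot_params(k_alpha = 1500, alpha = 0.019)
#' springpot_moduli(sp, c(0.1, 1, 10))
#' @export
springpot_moduli <- function(params, frequency_hz,
                             convention = c("hz", "rad_s")) {
  stopifnot(inherits(params, "springpot_params"))
  convention <- match_convention(convention)
  check_numeric(frequency_hz, "frequency_hz", positive = TRUE,
                increasing = TRUE)
  omega <- angular_frequency(frequency_hz, convention)
  mag <- params$k_alpha * omega^params$alpha
  phase <- params$alpha * pi / 2
  modulus_spectrum(frequency_hz,
                   storage_pa = mag * cos(phase),
                   loss_pa = mag * sin(phase),
                   convention = convention)
}

#' Storage and loss moduli of classical viscoelastic elements
#'
#' Baseline comparators built from springs and dashpots: the pure spring
#' (`G' = G`, `G'' = 0`), the pure dashpot (`G' = 0`, `G'' = eta * omega`),
#' the Kelvin-Voigt parallel pair (`G' = G`, `G'' = eta * omega`) and the
#' Maxwell series pair (`G' = G w^2 tau^2 / (1 + w^2 tau^2)`,
#' `G'' = G w tau / (1 + w^2 tau^2)` with `tau = eta / G`).
#'
#' @param params A [classical_params()].
#' @param frequency_hz Strictly increasing positive frequencies, Hz.
#' @param convention `"hz"` or `"rad_s"`; see [angular_frequency()].
#' @return A [modulus_spectrum()].
#' @export
classical_moduli <- function(params, frequency_hz,
                             convention = c("hz", "rad_s")) {
  stopifnot(inherits(params, "classical_params"))
  convention <- match_convention(convention)
  check_numeric(frequency_hz, "frequency_hz", positive = TRUE,
                increasing = TRUE)
  omega <- angular_frequency(frequency_hz, convention)
  g <- params$shear_modulus
  eta <- params$viscosity
  mod <- switch(params$kind,
    spring = list(storage = rep(g, length(omega)),
                  loss = rep(0, length(omega))),
    dashpot = list(storage = rep(0, length(omega)),
                   loss = eta * omega),
    kelvin_voigt = list(storage = rep(g, length(omega)),
                        loss = eta * omega),
    maxwell = {
      tau <- eta / g
      wt2 <- (omega * tau)^2
      list(storage = g * wt2 / (1 + wt2),
           loss = g * omega * tau / (1 + wt2))
    })
  modulus_spectrum(frequency_hz, mod$storage, mod$loss,
                   convention = convention)
}

#' Springpot relaxation modulus
#'
#' The response of a springpot to an ideal step shear strain is the power-law
#' relaxation modulus `G(t) = k_alpha * t^(-alpha) / gamma(1 - alpha)`. For
#' `alpha = 0` this is constant at `k_alpha`; `alpha = 1` is rejected because
#' the expression degenerates (pole of the gamma function at 0).
#'
#' @param params A [springpot_params()] with `alpha < 1`.
#' @param time_s Strictly increasing positive times, s.
#' @param step_strain Step strain amplitude stored with the trace
#'   (default 0.001, the 0.1 percent protocol).
#' @return A [relaxation_trace()] with `ramp_s = 0` (ideal step).
#' @examples
#' sp <- springpot_params(1500, 0.019)
#' springpot_relaxation(sp, c(1, 5, 10))
#' @export
springpot_relaxation <- function(params, time_s, step_strain = 0.001) {
  stopifnot(inherits(params, "springpot_params"))
  if (params$alpha >= 1) {
    stop_input("relaxation modulus degenerates at alpha = 1 ",
               "(gamma(1 - alpha) pole); use alpha < 1")
  }
  check_numeric(time_s, "time_s", positive = TRUE, increasing = TRUE)
  g <- params$k_alpha * time_s^(-params$alpha) / gamma(1 - params$alpha)
  relaxation_trace(time_s, g, step_strain = step_strain, ramp_s = 0)
}

#' Loss tangent of a springpot
#'
#' The ratio `G''/G' = tan(alpha * pi / 2)`, independent of frequency and of
#' `k_alpha`; a frequency-independent phase is the signature of the springpot.
#'
#' @param params A [springpot_params()] with `alpha < 1`.
#' @return The loss tangent, dimensionless.
#' @export
loss_tangent <- function(params) {
  stopifnot(inherits(params, "springpot_params"))
  if (params$alpha >= 1) {
    stop_input("loss tangent is infinite at alpha = 1")
  }
  tan(params$alpha * pi / 2)
}

#' Grunwald-Letnikov fractional derivative on a uniform grid
#'
#' Discretises the fractional derivative of order `alpha` of a strain history
#' sampled at spacing `dt` (history assumed zero before the first sample) as
#' the truncated sum `dt^(-alpha) * sum_j w_j * strain(t - j*dt)` with binomial
#' weights `w_0 = 1`, `w_j = w_{j-1} * (j - 1 - alpha) / j`. Multiplying the
#' result by `k_alpha` gives the springpot stress. The full history is kept
#' (no short-memory truncation); the convolution is evaluated by FFT. This is
#' a brute-force time-domain reference: as `dt -> 0` it converges to the
#' closed-form moduli and relaxation modulus, and it is used as the
#' independent oracle in the test suite.
#'
#' @param strain Dimensionless strain samples on a uniform grid.
#' @param alpha Fractional order in `[0, 1]`.
#' @param dt Grid spacing, s; strictly positive.
#' @param time_s Optional time stamps of the samples; if supplied they must be
#'   uniform with spacing `dt` (non-uniform grids are rejected).
#' @return Stress divided by `k_alpha`, same length as `strain`.
#' @examples
#' # alpha = 0 is the identity operator
#' gl_fractional_derivative(c(1, 2, 3), alpha = 0, dt = 0.1)
#' @export
gl_fractional_derivative <- function(strain, alpha, dt, time_s = NULL) {
  check_numeric(strain, "strain")
  check_numeric(alpha, "alpha", len = 1)
  if (alpha < 0 || alpha > 1) stop_input("'alpha' must lie in [0, 1]")
  check_numeric(dt, "dt", positive = TRUE, len = 1)
  if (!is.null(time_s)) {
    steps <- diff(time_s)
    if (any(abs(steps - dt) > 1e-9 * dt)) {
      stop_input("'time_s' is not a uniform grid with spacing 'dt'")
    }
  }
  n <- length(strain)
  j <- seq_len(n - 1)
  w <- c(1, cumprod((j - 1 - alpha) / j))
  # causal convolution sum_j w_j * strain_{i-j}, via FFT padded to a
  # highly composite length so long traces stay cheap
  m <- stats::nextn(2 * n)
  fw <- stats::fft(c(w, numeric(m - n)))
  fs <- stats::fft(c(strain, numeric(m - n)))
  out <- Re(stats::fft(fw * fs, inverse = TRUE))[seq_len(n)] / m
  out / dt^alpha
}

#' Simulated oscillatory springpot response via the Grunwald-Letnikov sum
#'
#' Drives the discretised fractional derivative with a sinusoidal strain and
#' extracts the steady-state in-phase and out-of-phase stress components,
#' giving a time-domain estimate of the storage and loss moduli at one
#' frequency. Used to cross-check the closed-form moduli.
#'
#' @param params A [springpot_params()].
#' @param frequency_hz Oscillation frequency, Hz.
#' @param convention `"hz"` or `"rad_s"`: interpretation of omega in the
#'   time-domain phase `sin(omega * t)`.
#' @param dt Time step, s.
#' @param cycles Number of cycles to simulate; the first `settle` cycles are
#'   discarded before the projection.
#' @param settle Cycles discarded as transient.
#' @return Named vector `c(storage_pa, loss_pa)`.
#' @export
gl_oscillatory_moduli <- function(params, frequency_hz,
                                  convention = c("hz", "rad_s"),
                                  dt = 1e-3, cycles = 10, settle = 5) {
  stopifnot(inherits(params, "springpot_params"))
  convention <- match_convention(convention)
  check_numeric(frequency_hz, "frequency_hz", positive = TRUE, len = 1)
  omega <- angular_frequency(frequency_hz, convention)
  period <- 2 * pi / omega
  t <- seq(dt, cycles * period, by = dt)
  strain <- sin(omega * t)
  stress <- params$k_alpha * gl_fractional_derivative(strain, params$alpha, dt)
  keep <- t > settle * period
  # project the steady-state stress onto the sin/cos basis of the drive
  basis <- cbind(sin(omega * t[keep]), cos(omega * t[keep]))
  coef <- stats::lsfit(basis, stress[keep], intercept = FALSE)$coefficients
  c(storage_pa = unname(coef[1]), loss_pa = unname(coef[2]))
}

#' Simulated step-strain response via the Grunwald-Letnikov sum
#'
#' Applies a step (optionally a finite linear ramp) of shear strain and
#' returns the resulting relaxation modulus trace, the time-domain reference
#' for [springpot_relaxation()] and for quantifying ramp sensitivity.
#'
#' @param params A [springpot_params()].
#' @param duration_s Total simulated time, s.
#' @param dt Time step, s.
#' @param step_strain Step amplitude, dimensionless.
#' @param ramp_s Ramp duration over which the strain rises linearly to
#'   `step_strain`; 0 gives an ideal step.
#' @return A [relaxation_trace()] on the simulation grid.
#' @export
gl_step_response <- function(params, duration_s, dt = 1e-3,
                             step_strain = 0.001, ramp_s = 0) {
  stopifnot(inherits(params, "springpot_params"))
  check_numeric(duration_s, "duration_s", positive = TRUE, len = 1)
  check_numeric(dt, "dt", positive = TRUE, len = 1)
  check_numeric(ramp_s, "ramp_s", nonneg = TRUE, len = 1)
  t <- seq(dt, duration_s, by = dt)
  strain <- if (ramp_s > 0) {
    step_strain * pmin(t / ramp_s, 1)
  } else {
    rep(step_strain, length(t))
  }
  stress <- params$k_alpha * gl_fractional_derivative(strain, params$alpha, dt)
  relaxation_trace(t, pmax(stress / step_strain, 0),
                   step_strain = step_strain, ramp_s = ramp_s)
}
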