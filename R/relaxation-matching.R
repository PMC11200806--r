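# Prediction vs measurement of stress relaxation, and organ-to-phantom
# matching on the frequency-domain storage modulus.

window_mean <- function(trace, window, n_grid = 201) {
  grid <- seq(window[1], window[2], length.out = n_grid)
  mean(stats::approx(trace$time_s, trace$relaxation_modulus_pa,
                     xout = grid)$y)
}

#' Compare a predicted relaxation trace with a measured one
#'
#' Both traces are linearly interpolated onto a common uniform grid over the
#' comparison window and time-averaged; the statistic is the signed percent
#' difference `100 * (mean(predicted) - mean(measured)) / mean(measured)`.
#' The default window of 1 to 10 s sits after the ~1 s strain ramp and within
#' the usual display decade of relaxation tests.
#'
#' @param predicted,measured [relaxation_trace()] objects whose time supports
#'   both cover `window`.
#' @param window Comparison window `c(t_start, t_end)` in s.
#' @return A list of class `relaxation_comparison`: `percent_difference`
#'   (signed), `window`, `predicted_mean_pa`, `measured_mean_pa`.
#' @export
compare_relaxation <- function(predicted, measured, window = c(1, 10)) {
  stopifnot(inherits(predicted, "relaxation_trace"),
            inherits(measured, "relaxation_trace"))
  check_numeric(window, "window", positive = TRUE, len = 2)
  if (window[2] <= window[1]) stop_input("'window' must be increasing")
  for (tr in list(predicted, measured)) {
    if (min(tr$time_s) > window[1] || max(tr$time_s) < window[2]) {
      stop_input("both traces must cover the comparison window [",
                 window[1], ", ", window[2], "] s")
    }
  }
  pm <- window_mean(predicted, window)
  mm <- window_mean(measured, window)
  if (mm <= 0) stop_input("measured mean must be positive")
  structure(list(percent_difference = 100 * (pm - mm) / mm,
                 window = window, predicted_mean_pa = pm,
                 measured_mean_pa = mm),
            class = "relaxation_comparison")
}

#' @export
print.relaxation_comparison <- function(x, ...) {
  cat(sprintf(
    "relaxation comparison over [%g, %g] s: predicted %.4g Pa vs measured %.4g Pa (%+.1f%%)\n",
    x$window[1], x$window[2], x$predicted_mean_pa, x$measured_mean_pa,
    x$percent_difference))
  invisible(x)
}

#' Match each organ to its closest phantom concentration
#'
#' Assigns every organ the candidate gel concentration whose storage modulus
#' (at a common reference condition, e.g. 0.1 Hz and 0.1 percent shear
#' strain) is closest in log-ratio distance `|log(candidate / organ)|`. Ties
#' break toward the lower concentration. The log-ratio metric makes the
#' assignment invariant to rescaling all moduli by a common factor.
#'
#' @param organ_values Named numeric vector: organ -> storage modulus (Pa or
#'   kPa, consistently) at the reference condition.
#' @param candidates Named numeric vector: concentration (percent, names
#'   coercible to numeric) -> storage modulus at the same condition.
#' @return A list of class `match_report`: `assignments` (organ ->
#'   concentration percent), `discrepancy_pct` (organ -> 100 * |candidate -
#'   organ| / organ), `criterion`.
#' @examples
#' match_phantom(c(heart = 1400, kidney = 600, liver = 200),
#'               c("0.25" = 400, "0.3" = 700, "0.4" = 1400))
#' @export
match_phantom <- function(organ_values, candidates) {
  if (length(candidates) == 0) stop_input("empty candidate set")
  check_numeric(organ_values, "organ_values", positive = TRUE)
  check_numeric(candidates, "candidates", positive = TRUE)
  if (is.null(names(organ_values)) || is.null(names(candidates))) {
    stop_input("'organ_values' and 'candidates' must be named")
  }
  conc <- as.numeric(names(candidates))
  if (anyNA(conc)) stop_input("candidate names must be concentrations")
  ord <- order(conc)
  conc <- conc[ord]
  cand <- unname(candidates[ord])
  assignments <- numeric(length(organ_values))
  discrepancy <- numeric(length(organ_values))
  for (i in seq_along(organ_values)) {
    d <- abs(log(cand / organ_values[i]))
    # which.min takes the first minimum; candidates are sorted ascending, so
    # ties resolve toward the lower concentration
    best <- which.min(round(d, 12))
    assignments[i] <- conc[best]
    discrepancy[i] <- 100 * abs(cand[best] - organ_values[i]) /
      organ_values[i]
  }
  names(assignments) <- names(organ_values)
  names(discrepancy) <- names(organ_values)
  structure(list(assignments = assignments, discrepancy_pct = discrepancy,
                 criterion = "min |log(candidate/organ)| on storage modulus"),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("phantom matching (", x$criterion, ")\n", sep = "")
  for (organ in names(x$assignments)) {
    cat(sprintf("  %-8s -> %g%% agarose (discrepancy %.1f%%)\n", organ,
                x$assignments[organ], x$discrepancy_pct[organ]))
  }
  invisible(x)
}

fmt_kpa <- function(pa) sprintf("%.1f", pa / 1000)
fmt_alpha <- function(a) sprintf("%.3f", a)

#' Assemble the study report
#'
#' Collates per-concentration springpot fits, pre-compression models,
#' relaxation comparisons and the organ matching into a set of data frames
#' formatted like the study's summary tables: moduli in kPa to one decimal,
#' fractional orders to three decimals.
#'
#' @param fits Named list (by concentration percent) of `springpot_fit`
#'   objects or [springpot_params()] (fits at contact force).
#' @param precompression Named list (by concentration percent) of
#'   [precompression_model()] objects.
#' @param comparisons Named list (by sample label) of
#'   `relaxation_comparison` objects.
#' @param match A `match_report`, or `NULL`.
#' @param moduli Optional data frame of reference-condition storage moduli
#'   with columns `sample`, `condition`, `storage_pa`.
#' @return A list of class `study_report` with data frames `springpot`,
#'   `precompression`, `relaxation`, `match`, `moduli` (empty but with
#'   headers when the corresponding input is empty).
#' @export
build_report <- function(fits = list(), precompression = list(),
                         comparisons = list(), match = NULL, moduli = NULL) {
  params_of <- function(x) if (inherits(x, "springpot_fit")) x$params else x
  springpot_df <- data.frame(concentration_pct = numeric(0),
                             k_alpha_kpa = character(0),
                             alpha = character(0),
                             correlation = numeric(0))
  if (length(fits)) {
    springpot_df <- data.frame(
      concentration_pct = as.numeric(names(fits)),
      k_alpha_kpa = vapply(fits, function(x) fmt_kpa(params_of(x)$k_alpha),
                           ""),
      alpha = vapply(fits, function(x) fmt_alpha(params_of(x)$alpha), ""),
      correlation = vapply(fits, function(x) {
        if (inherits(x, "springpot_fit")) x$correlation else NA_real_
      }, 0),
      row.names = NULL)
  }
  precomp_df <- data.frame(concentration_pct = numeric(0),
                           k0_kpa = character(0), b_per_pct = character(0),
                           alpha = character(0))
  if (length(precompression)) {
    precomp_df <- data.frame(
      concentration_pct = as.numeric(names(precompression)),
      k0_kpa = vapply(precompression, function(m) fmt_kpa(m$k0), ""),
      b_per_pct = vapply(precompression, function(m) sprintf("%.3f", m$b), ""),
      alpha = vapply(precompression, function(m) fmt_alpha(m$alpha), ""),
      row.names = NULL)
  }
  relax_df <- data.frame(sample = character(0),
                         percent_difference = character(0),
                         predicted_kpa = character(0),
                         measured_kpa = character(0))
  if (length(comparisons)) {
    relax_df <- data.frame(
      sample = names(comparisons),
      percent_difference = vapply(comparisons, function(x) {
        sprintf("%+.1f", x$percent_difference)
      }, ""),
      predicted_kpa = vapply(comparisons, function(x) {
        fmt_kpa(x$predicted_mean_pa)
      }, ""),
      measured_kpa = vapply(comparisons, function(x) {
        fmt_kpa(x$measured_mean_pa)
      }, ""),
      row.names = NULL)
  }
  match_df <- data.frame(organ = character(0),
                         concentration_pct = numeric(0),
                         discrepancy_pct = character(0))
  if (!is.null(match)) {
    match_df <- data.frame(
      organ = names(match$assignments),
      concentration_pct = unname(match$assignments),
      discrepancy_pct = sprintf("%.1f", unname(match$discrepancy_pct)),
      row.names = NULL)
  }
  moduli_df <- if (is.null(moduli)) {
    data.frame(sample = character(0), condition = character(0),
               storage_kpa = character(0))
  } else {
    data.frame(sample = moduli$sample, condition = moduli$condition,
               storage_kpa = fmt_kpa(moduli$storage_pa), row.names = NULL)
  }
  structure(list(springpot = springpot_df, precompression = precomp_df,
                 relaxation = relax_df, match = match_df,
                 moduli = moduli_df),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  for (name in names(x)) {
    cat("==", name, "==\n")
    if (nrow(x[[name]])) print(x[[name]], row.names = FALSE) else cat("(empty)\n")
    cat("\n")
  }
  invisible(x)
}
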