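# End-to-end orchestration: LVE limits -> inertial cutoffs -> springpot fits
# -> contact offset -> pre-compression model -> concentration power law ->
# relaxation prediction and comparison -> organ/phantom matching -> report.

#' Load a directory of CSV records into a study dataset
#'
#' Scans `dir` for files in the package CSV dialect, classifies each by its
#' declared `record_kind`, and groups records by sample (agarose samples by
#' concentration, organs by material). Frequency sweeps are keyed by their
#' recorded total axial strain.
#'
#' @param dir Directory containing record CSV files.
#' @return A list shaped like [gen_study()] output (without `truth`).
#' @export
read_study <- function(dir) {
  paths <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(paths) == 0) stop_input("no records found in ", dir)
  out <- list(strain_sweeps = list(), frequency_sweeps = list(),
              uniaxial = list(), relaxation = list())
  for (path in paths) {
    first <- readLines(path, n = 1)
    kind <- sub("^#\\s*record_kind=", "", first)
    if (!kind %in% names(record_columns)) {
      stop_input("cannot classify ", path, ": bad or missing record_kind")
    }
    rec <- read_records(path, kind)
    meta <- rec$meta
    key <- if (!is.null(meta) && meta$material == "agarose") {
      as.character(meta$concentration_pct)
    } else if (!is.null(meta)) {
      meta$material
    } else {
      tools::file_path_sans_ext(basename(path))
    }
    switch(kind,
      strain_sweep = out$strain_sweeps[[key]] <- rec,
      frequency_sweep = {
        lvl <- as.character(rec$axial_strain_pct)
        out$frequency_sweeps[[key]][[lvl]] <- rec
      },
      uniaxial = out$uniaxial[[key]] <- rec,
      relaxation = out$relaxation[[key]] <- rec)
  }
  out
}

interp_log <- function(x, y, x0) {
  stats::approx(log(x), y, xout = log(x0), rule = 2)$y
}

is_organ_key <- function(key) key %in% c("heart", "kidney", "liver")

#' Run the full analysis pipeline
#'
#' Executes the study analysis on a dataset that is either simulated in
#' memory ([gen_study()]) or loaded from a directory of CSV records
#' ([read_study()]); the stages are, in order: LVE limit detection on
#' amplitude sweeps, inertial cutoff detection and truncation of frequency
#' sweeps, springpot fitting per sample and axial strain (joint channels for
#' gels, storage-only for organs), Young modulus and contact-force axial
#' strain offset, the linear pre-compression fit of the coefficient of
#' consistence, the concentration power law, relaxation prediction from the
#' contact-force fits and comparison with measured traces, organ-to-phantom
#' matching on the storage modulus at the reference condition (0.1 Hz, 0.1
#' percent strain), and report assembly. Axial strains on frequency sweeps
#' are totals (contact offset included); the offset is recomputed from the
#' uniaxial records for the report. Any stage failure propagates with the
#' stage name and sample attached.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised keys: `seed`, `convention` (`"hz"`/`"rad_s"`),
#'   `output_dir`, `window` (two numbers, s), `lve_tolerance`,
#'   `drop_fraction`, `default_young_modulus_kpa`, and either `simulate:`
#'   (arguments forwarded to [study_config()]) or `data_dir:` (directory of
#'   CSV records).
#' @param seed Optional override of the config seed.
#' @param verbose Log each stage to standard error.
#' @return Invisibly, a list with the `study_report`, the per-stage
#'   intermediate results, and the paths written (when `output_dir` is set).
#' @export
run_pipeline <- function(config, seed = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop_input("config must be a file path or a list")
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed %||% 1)
  convention <- match_convention(cfg$convention %||% "hz")
  window <- as.numeric(cfg$window %||% c(1, 10))
  lve_tol <- cfg$lve_tolerance %||% 0.05
  drop_frac <- cfg$drop_fraction %||% 0.1
  default_e_pa <- 1000 * (cfg$default_young_modulus_kpa %||% 4.4)
  log_stage <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- function(name, sample, expr) {
    tryCatch(expr, error = function(e) {
      stop_input(sprintf("stage '%s' failed for sample '%s': %s", name,
                         sample, conditionMessage(e)))
    })
  }

  data <- if (!is.null(cfg$simulate)) {
    args <- cfg$simulate
    args$seed <- cfg$seed
    args$convention <- convention
    if (!is.null(args$power_law)) {
      args$power_law <- do.call(concentration_power_law, args$power_law)
    }
    log_stage("simulating study (seed ", cfg$seed, ", ", convention,
              " convention)")
    gen_study(do.call(study_config, args))
  } else if (!is.null(cfg$data_dir)) {
    log_stage("loading records from ", cfg$data_dir)
    read_study(cfg$data_dir)
  } else {
    stop_input("config needs either 'simulate' or 'data_dir'")
  }
  n_records <- length(data$strain_sweeps) + length(data$uniaxial) +
    length(data$relaxation) + sum(lengths(data$frequency_sweeps))
  if (n_records == 0) stop_input("no records to analyse")
  log_stage(n_records, " records loaded")

  # LVE limits from amplitude sweeps
  lve <- lapply(names(data$strain_sweeps), function(key) {
    stage("detect_lve_limit", key,
          detect_lve_limit(data$strain_sweeps[[key]], lve_tol))
  })
  names(lve) <- names(data$strain_sweeps)
  log_stage("LVE limits: ",
            paste(names(lve), sprintf("%.3g%%", unlist(lve)),
                  collapse = ", "))

  # cutoffs, truncation, springpot fits per sample and axial strain
  fits <- list()
  cutoffs <- list()
  for (key in names(data$frequency_sweeps)) {
    channels <- if (is_organ_key(key)) "storage_only" else "joint"
    fits[[key]] <- list()
    for (lvl in names(data$frequency_sweeps[[key]])) {
      sweep <- data$frequency_sweeps[[key]][[lvl]]
      cut <- stage("detect_inertial_cutoff", key,
                   detect_inertial_cutoff(sweep, drop_frac))
      cutoffs[[key]] <- cut
      spec <- as_spectrum(stage("truncate", key,
                                truncate_at_cutoff(sweep, cut)), convention)
      fits[[key]][[lvl]] <- stage("fit_springpot", key,
                                  fit_springpot(spec, channels = channels))
    }
    log_stage("fitted ", length(fits[[key]]), " axial level(s) for ", key,
              " (cutoff ", format(cutoffs[[key]]), " Hz)")
  }

  # Young moduli and contact-force offsets
  young <- list()
  offsets <- list()
  for (key in names(data$frequency_sweeps)) {
    if (is_organ_key(key)) next
    e_pa <- if (!is.null(data$uniaxial[[key]])) {
      stage("young_modulus", key, young_modulus(data$uniaxial[[key]]))
    } else {
      default_e_pa
    }
    young[[key]] <- e_pa
    meta <- data$frequency_sweeps[[key]][[1]]$meta
    offsets[[key]] <- stage("axial_strain_offset", key,
                            axial_strain_offset(meta$contact_force_n,
                                                meta$diameter_mm, e_pa))
  }

  # pre-compression model per gel concentration
  precomp <- list()
  for (key in names(fits)) {
    if (is_organ_key(key) || length(fits[[key]]) < 3) next
    k <- vapply(fits[[key]], function(f) f$params$k_alpha, 0)
    a <- vapply(fits[[key]], function(f) f$params$alpha, 0)
    strains <- vapply(names(fits[[key]]), function(lvl) {
      data$frequency_sweeps[[key]][[lvl]]$axial_strain_pct
    }, 0)
    precomp[[key]] <- stage("fit_precompression", key,
                            fit_precompression(strains, k, a))
  }

  # concentration power law from plateau storage moduli at 0.1% strain, 1 Hz
  gel_keys <- names(data$strain_sweeps)[!is_organ_key(names(data$strain_sweeps))]
  power_law <- NULL
  if (length(gel_keys) >= 3) {
    plateau_kpa <- vapply(gel_keys, function(key) {
      sw <- data$strain_sweeps[[key]]
      interp_log(sw$strain_pct, sw$storage_pa, 0.1) / 1000
    }, 0)
    power_law <- stage("fit_concentration_power_law", "all",
                       fit_concentration_power_law(as.numeric(gel_keys),
                                                   plateau_kpa))
    log_stage(sprintf("power law: %.3g kPa * c^%.3g",
                      power_law$amplitude_kpa, power_law$exponent))
  }

  # relaxation prediction (contact-force fit) vs measured traces
  contact_fit <- function(key) {
    lvls <- names(fits[[key]])
    strains <- vapply(lvls, function(lvl) {
      data$frequency_sweeps[[key]][[lvl]]$axial_strain_pct
    }, 0)
    fits[[key]][[lvls[which.min(strains)]]]
  }
  comparisons <- list()
  for (key in names(data$relaxation)) {
    if (is_organ_key(key) || is.null(fits[[key]])) next
    measured <- data$relaxation[[key]]
    fit <- contact_fit(key)
    predicted <- stage("springpot_relaxation", key,
                       springpot_relaxation(fit$params, measured$time_s,
                                            step_strain = measured$step_strain))
    comparisons[[key]] <- stage("compare_relaxation", key,
                                compare_relaxation(predicted, measured,
                                                   window))
  }
  if (length(comparisons)) {
    log_stage("relaxation differences: ",
              paste(names(comparisons),
                    sprintf("%+.1f%%",
                            vapply(comparisons,
                                   function(x) x$percent_difference, 0)),
                    collapse = ", "))
  }

  # organ-to-phantom matching on G' at 0.1 Hz, 0.1% strain
  g_at <- function(fit, f_hz) {
    springpot_moduli(fit$params, f_hz, fit$convention)$storage_pa
  }
  organ_keys <- names(fits)[is_organ_key(names(fits))]
  match <- NULL
  if (length(organ_keys) && length(fits) > length(organ_keys)) {
    organ_values <- vapply(organ_keys, function(key) g_at(contact_fit(key),
                                                          0.1), 0)
    cand_keys <- setdiff(names(fits), organ_keys)
    candidates <- vapply(cand_keys, function(key) g_at(contact_fit(key),
                                                       0.1), 0)
    match <- stage("match_phantom", "all",
                   match_phantom(organ_values, candidates))
    log_stage("matching: ",
              paste(names(match$assignments), "->",
                    paste0(match$assignments, "%"), collapse = ", "))
  }

  # reference-condition moduli table
  moduli <- do.call(rbind, c(
    lapply(names(fits), function(key) {
      data.frame(sample = if (is_organ_key(key)) key
                 else paste0(key, "% agarose"),
                 condition = "0.1Hz_0.1pct",
                 storage_pa = g_at(contact_fit(key), 0.1))
    }),
    lapply(names(data$strain_sweeps), function(key) {
      sw <- data$strain_sweeps[[key]]
      data.frame(sample = if (is_organ_key(key)) key
                 else paste0(key, "% agarose"),
                 condition = "1Hz_0.01pct",
                 storage_pa = interp_log(sw$strain_pct, sw$storage_pa, 0.01))
    })))

  gel_fit_keys <- setdiff(names(fits), organ_keys)
  report <- build_report(
    fits = stats::setNames(lapply(gel_fit_keys, contact_fit), gel_fit_keys),
    precompression = precomp, comparisons = comparisons, match = match,
    moduli = moduli)

  written <- character(0)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (name in names(report)) {
      path <- file.path(cfg$output_dir, paste0(name, ".csv"))
      utils::write.csv(report[[name]], path, row.names = FALSE)
      written <- c(written, path)
    }
    summary_path <- file.path(cfg$output_dir, "summary.txt")
    writeLines(utils::capture.output(print(report)), summary_path)
    written <- c(written, summary_path)
    log_stage("report written to ", cfg$output_dir)
  }

  invisible(list(report = report, lve_limits = lve, cutoffs = cutoffs,
                 fits = fits, young_modulus = young, offsets = offsets,
                 precompression = precomp, power_law = power_law,
                 comparisons = comparisons, match = match,
                 written = written, convention = convention,
                 data = data))
}
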