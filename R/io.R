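# CSV record format. One record kind per file; comma separated, "." decimal;
# "#"-prefixed header lines carry the record kind, units and sample metadata
# as key=value pairs; data columns follow in a canonical order.

record_columns <- list(
  strain_sweep = c("strain_pct", "storage_pa", "loss_pa"),
  frequency_sweep = c("frequency_hz", "storage_pa", "loss_pa"),
  uniaxial = c("strain", "stress_pa"),
  relaxation = c("time_s", "relaxation_modulus_pa"))

unit_scale <- c(Pa = 1, kPa = 1000, Hz = 1, s = 1, percent = 1, none = 1)

default_units <- list(
  strain_sweep = c(strain = "percent", modulus = "Pa"),
  frequency_sweep = c(frequency = "Hz", modulus = "Pa"),
  uniaxial = c(strain = "none", stress = "Pa"),
  relaxation = c(time = "s", modulus = "Pa"))

meta_header <- function(meta) {
  if (is.null(meta)) return(character(0))
  fields <- c("sample_id", "material", "concentration_pct", "diameter_mm",
              "thickness_mm", "contact_force_n")
  vapply(fields, function(f) {
    v <- meta[[f]]
    if (is.null(v)) "" else sprintf("# %s=%s", f, format(v, digits = 15))
  }, "")
}

num_fmt <- function(x) sprintf("%.12g", x)

#' Write a measurement record to CSV
#'
#' Writes a record in the package's CSV dialect: "#"-prefixed header lines
#' carrying the record kind, units and sample metadata as `key=value` pairs,
#' then the canonical data columns. Output is deterministic: writing the same
#' record twice yields byte-identical files.
#'
#' @param record A [strain_sweep()], [frequency_sweep()],
#'   [uniaxial_record()] or [relaxation_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(record, path) {
  kind <- switch(class(record)[1],
                 strain_sweep = "strain_sweep",
                 frequency_sweep = "frequency_sweep",
                 uniaxial_record = "uniaxial",
                 relaxation_trace = "relaxation",
                 stop_input("unsupported record class: ", class(record)[1]))
  cols <- record_columns[[kind]]
  data <- switch(kind,
    strain_sweep = data.frame(strain_pct = record$strain_pct,
                              storage_pa = record$storage_pa,
                              loss_pa = record$loss_pa),
    frequency_sweep = data.frame(frequency_hz = record$frequency_hz,
                                 storage_pa = record$storage_pa,
                                 loss_pa = record$loss_pa),
    uniaxial = data.frame(strain = record$strain,
                          stress_pa = record$stress_pa),
    relaxation = data.frame(time_s = record$time_s,
                            relaxation_modulus_pa =
                              record$relaxation_modulus_pa))
  if (nrow(data) == 0) stop_input("refusing to write an empty record")
  units <- default_units[[kind]]
  extra <- switch(kind,
    strain_sweep = sprintf("# frequency_hz=%s", num_fmt(record$frequency_hz)),
    frequency_sweep = c(
      sprintf("# shear_strain_pct=%s", num_fmt(record$shear_strain_pct)),
      sprintf("# axial_strain_pct=%s", num_fmt(record$axial_strain_pct))),
    relaxation = c(sprintf("# step_strain=%s", num_fmt(record$step_strain)),
                   sprintf("# ramp_s=%s", num_fmt(record$ramp_s))),
    character(0))
  header <- c(sprintf("# record_kind=%s", kind),
              sprintf("# units: %s",
                      paste(names(units), units, sep = "=",
                            collapse = ",")),
              meta_header(record$meta), extra)
  header <- header[nzchar(header)]
  body <- c(paste(cols, collapse = ","),
            apply(data, 1, function(r) paste(num_fmt(r), collapse = ",")))
  writeLines(c(header, body), path)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- list()
  units <- NULL
  for (line in lines) {
    txt <- sub("^#\\s*", "", line)
    if (startsWith(txt, "units:")) {
      pairs <- strsplit(sub("^units:\\s*", "", txt), ",")[[1]]
      units <- vapply(strsplit(pairs, "="), `[`, "", 2)
      names(units) <- vapply(strsplit(pairs, "="), `[`, "", 1)
    } else if (grepl("=", txt, fixed = TRUE)) {
      eq <- regexpr("=", txt, fixed = TRUE)
      kv[[trimws(substr(txt, 1, eq - 1))]] <-
        trimws(substr(txt, eq + 1, nchar(txt)))
    }
  }
  list(kv = kv, units = units)
}

scale_of <- function(units, quantity, kind) {
  token <- if (!is.null(units) && quantity %in% names(units)) {
    units[[quantity]]
  } else {
    default_units[[kind]][[quantity]]
  }
  if (!token %in% names(unit_scale)) {
    stop_input("unknown unit token '", token, "' for ", quantity)
  }
  unit_scale[[token]]
}

meta_from_header <- function(kv) {
  if (is.null(kv$sample_id) || is.null(kv$material)) return(NULL)
  sample_meta(sample_id = kv$sample_id, material = kv$material,
              concentration_pct = if (!is.null(kv$concentration_pct)) {
                as.numeric(kv$concentration_pct)
              },
              diameter_mm = as.numeric(kv$diameter_mm %||% 25),
              thickness_mm = as.numeric(kv$thickness_mm %||% 5.5),
              contact_force_n = as.numeric(kv$contact_force_n %||% 0.1))
}

#' Read a measurement record from CSV
#'
#' Reads a file written in the package's CSV dialect (see [write_records()]),
#' checks that the file's declared kind matches `kind`, validates the schema
#' (naming any missing column), and normalises units to Pa/Hz/s/percent
#' (moduli and stresses declared in kPa are converted).
#'
#' @param path Input file path.
#' @param kind One of `"strain_sweep"`, `"frequency_sweep"`, `"uniaxial"`,
#'   `"relaxation"`.
#' @return The corresponding typed record.
#' @export
read_records <- function(path, kind = c("strain_sweep", "frequency_sweep",
                                        "uniaxial", "relaxation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  hdr <- parse_header(lines[startsWith(lines, "#")])
  declared <- hdr$kv$record_kind
  if (is.null(declared) || declared != kind) {
    stop_input("file declares record_kind '", declared %||% "<missing>",
               "' but '", kind, "' was requested")
  }
  data <- utils::read.csv(textConnection(
    lines[!startsWith(lines, "#")]), check.names = FALSE)
  missing <- setdiff(record_columns[[kind]], names(data))
  if (length(missing)) {
    stop_input("missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  meta <- meta_from_header(hdr$kv) %||% default_meta()
  u <- hdr$units
  switch(kind,
    strain_sweep = strain_sweep(
      meta,
      strain_pct = data$strain_pct * scale_of(u, "strain", kind),
      storage_pa = data$storage_pa * scale_of(u, "modulus", kind),
      loss_pa = data$loss_pa * scale_of(u, "modulus", kind),
      frequency_hz = as.numeric(hdr$kv$frequency_hz %||% 1)),
    frequency_sweep = frequency_sweep(
      meta,
      frequency_hz = data$frequency_hz * scale_of(u, "frequency", kind),
      storage_pa = data$storage_pa * scale_of(u, "modulus", kind),
      loss_pa = data$loss_pa * scale_of(u, "modulus", kind),
      shear_strain_pct = as.numeric(hdr$kv$shear_strain_pct %||% 0.1),
      axial_strain_pct = as.numeric(hdr$kv$axial_strain_pct %||% 0)),
    uniaxial = uniaxial_record(
      meta, strain = data$strain,
      stress_pa = data$stress_pa * scale_of(u, "stress", kind)),
    relaxation = relaxation_trace(
      time_s = data$time_s * scale_of(u, "time", kind),
      relaxation_modulus_pa = data$relaxation_modulus_pa *
        scale_of(u, "modulus", kind),
      step_strain = as.numeric(hdr$kv$step_strain %||% 0.001),
      ramp_s = as.numeric(hdr$kv$ramp_s %||% 1), meta = meta))
}

#' Write a full synthetic study to a directory of CSV records
#'
#' Materialises every record of a [gen_study()] dataset in the package CSV
#' dialect, one file per record, and returns a manifest data frame.
#'
#' @param study A `study_data` object from [gen_study()].
#' @param dir Output directory (created if needed).
#' @return Data frame with columns `path`, `kind`, `sample`, `axial_strain_pct`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(record, name, kind, sample, axial = NA_real_) {
    path <- file.path(dir, name)
    write_records(record, path)
    manifest[[length(manifest) + 1]] <<-
      data.frame(path = path, kind = kind, sample = sample,
                 axial_strain_pct = axial)
  }
  for (key in names(study$strain_sweeps)) {
    add(study$strain_sweeps[[key]],
        sprintf("strain_sweep_%s.csv", key), "strain_sweep", key)
  }
  for (key in names(study$frequency_sweeps)) {
    for (lvl in names(study$frequency_sweeps[[key]])) {
      rec <- study$frequency_sweeps[[key]][[lvl]]
      add(rec, sprintf("frequency_sweep_%s_axial%s.csv", key, lvl),
          "frequency_sweep", key, rec$axial_strain_pct)
    }
  }
  for (key in names(study$uniaxial)) {
    add(study$uniaxial[[key]], sprintf("uniaxial_%s.csv", key), "uniaxial",
        key)
  }
  for (key in names(study$relaxation)) {
    add(study$relaxation[[key]], sprintf("relaxation_%s.csv", key),
        "relaxation", key)
  }
  do.call(rbind, manifest)
}
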