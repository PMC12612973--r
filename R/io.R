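## CSV dialect: comma separator, period decimal, UTF-8, '#' metadata lines.

.schemas <- list(
  trace = c("time_h", "signal", "replicate"),
  titration = c("q_conc_M", "f_area", "temperature_C"),
  spectrum = c("wavelength_nm", "intensity"),
  dose_response = c("dose_uM", "response"),
  dls_distribution = c("rh_nm", "intensity"),
  dls_autocorrelation = c("lag_s", "g2_minus_1")
)

## internal: read a CSV, check header and numeric cells against a schema
.read_schema <- function(path, schema_name) {
  required <- .schemas[[schema_name]]
  if (is.null(required))
    .validation_error(sprintf("unknown schema '%s'", schema_name))
  if (!file.exists(path))
    .validation_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) .validation_error(
      sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0)
    .validation_error(sprintf("%s: no data rows", path))
  missing <- setdiff(required, names(df))
  if (length(missing))
    .validation_error(sprintf("%s: missing required column(s): %s",
                              path, paste(missing, collapse = ", ")))
  numeric_cols <- setdiff(names(df), "replicate")
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      .validation_error(sprintf("%s: non-numeric value in column '%s', row %d",
                                path, col, bad[1]))
    if (anyNA(v))
      .validation_error(sprintf("%s: missing value in column '%s', row %d",
                                path, col, which(is.na(v))[1]))
    df[[col]] <- v
  }
  df
}

## internal: '#' key=value metadata lines at the top of a file
.read_metadata <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2)
      out[[trimws(kv[1])]] <- suppressWarnings(as.numeric(trimws(kv[2])))
  }
  out
}

#' Read aggregation traces from CSV
#'
#' Expects columns `time_h, signal, replicate` (and optionally `blank`);
#' one [kinetic_trace()] is built per replicate label, in order of first
#' appearance.
#'
#' @param path CSV file path.
#' @return Named list of raw [kinetic_trace()] objects.
#' @export
read_trace_csv <- function(path) {
  df <- .read_schema(path, "trace")
  reps <- unique(as.character(df$replicate))
  out <- lapply(reps, function(r) {
    sub <- df[as.character(df$replicate) == r, ]
    if (any(diff(sub$time_h) <= 0))
      .validation_error(sprintf(
        "%s: time_h not strictly increasing within replicate '%s'", path, r))
    blank <- if ("blank" %in% names(sub)) sub$blank[1] else NULL
    kinetic_trace(sub$time_h, sub$signal, replicate_id = r, blank = blank)
  })
  names(out) <- reps
  out
}

#' Read a quencher titration from CSV
#'
#' Expects columns `q_conc_M, f_area, temperature_C` and optionally
#' `a_ex, a_em`.  All rows must share one temperature.
#'
#' @param path CSV file path.
#' @return A [quench_titration()].
#' @export
read_titration_csv <- function(path) {
  df <- .read_schema(path, "titration")
  if (length(unique(df$temperature_C)) != 1)
    .validation_error(sprintf("%s: multiple temperatures in one titration",
                              path))
  quench_titration(df$q_conc_M, df$f_area, df$temperature_C[1],
                   a_ex = if ("a_ex" %in% names(df)) df$a_ex else NULL,
                   a_em = if ("a_em" %in% names(df)) df$a_em else NULL)
}

#' Read an emission spectrum from CSV
#'
#' Expects columns `wavelength_nm, intensity`; optional `#` metadata
#' lines `excitation_nm` and `temperature_C`.
#'
#' @param path CSV file path.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- .read_schema(path, "spectrum")
  meta <- .read_metadata(path)
  emission_spectrum(df$wavelength_nm, df$intensity,
                    excitation_nm = meta$excitation_nm %||% 275,
                    temperature_c = meta$temperature_C %||% 25)
}

#' Read a dose-response table from CSV
#'
#' Expects columns `dose_uM, response`.
#'
#' @param path CSV file path.
#' @return Data frame with `dose_uM`, `response`.
#' @export
read_dose_response_csv <- function(path) {
  .read_schema(path, "dose_response")[, c("dose_uM", "response")]
}

#' Read a DLS size distribution from CSV
#'
#' Expects columns `rh_nm, intensity`.
#'
#' @param path CSV file path.
#' @return A [size_distribution()].
#' @export
read_dls_distribution_csv <- function(path) {
  df <- .read_schema(path, "dls_distribution")
  size_distribution(df$rh_nm, df$intensity)
}

#' Read a DLS autocorrelation curve from CSV
#'
#' Expects columns `lag_s, g2_minus_1` plus `#` metadata lines for the
#' instrument geometry (`wavelength_nm`, `angle_deg`,
#' `refractive_index`, `temperature_C`, `viscosity_Pa_s`); defaults are
#' used for any missing entry.
#'
#' @param path CSV file path.
#' @return An [autocorrelation_curve()].
#' @export
read_dls_autocorrelation_csv <- function(path) {
  df <- .read_schema(path, "dls_autocorrelation")
  meta <- .read_metadata(path)
  autocorrelation_curve(df$lag_s, df$g2_minus_1,
                        wavelength_nm = meta$wavelength_nm %||% 633,
                        angle_deg = meta$angle_deg %||% 90,
                        refractive_index = meta$refractive_index %||% 1.33,
                        temperature_c = meta$temperature_C %||% 25,
                        viscosity_pa_s = meta$viscosity_Pa_s %||% 8.9e-4)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Validate and load an input file against a named schema
#'
#' Single dispatch point over the typed readers: checks the file exists,
#' the header matches the schema, and every cell parses as its declared
#' type, with errors naming the offending row and column.
#'
#' @param path CSV file path.
#' @param schema_name One of `"trace"`, `"titration"`, `"spectrum"`,
#'   `"dose_response"`, `"dls_distribution"`, `"dls_autocorrelation"`.
#' @return The typed object the matching `read_*` function returns.
#' @export
validate_and_load <- function(path, schema_name) {
  switch(schema_name,
         trace = read_trace_csv(path),
         titration = read_titration_csv(path),
         spectrum = read_spectrum_csv(path),
         dose_response = read_dose_response_csv(path),
         dls_distribution = read_dls_distribution_csv(path),
         dls_autocorrelation = read_dls_autocorrelation_csv(path),
         .validation_error(sprintf("unknown schema '%s'", schema_name)))
}

#' Write a replicate kinetics fit table to CSV
#'
#' Writes the per-replicate + mean/sd parameter table of a
#' [fit_aggregation_replicates()] result with the standard columns
#' `replicate, rho, k_per_h, kn_per_h, ke_per_M_h, t0_h, thalf_h, t1_h,
#' r_squared`.
#'
#' @param group An `agg_fit_group`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_fit_csv <- function(group, path) {
  stopifnot(inherits(group, "agg_fit_group"))
  utils::write.csv(group$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-temperature binding report to CSV
#'
#' One row per temperature with columns `temperature_C, ksv_per_M,
#' kq_per_M_s, kb_per_M, n_apparent, r2_sv, r2_binding`, followed by
#' `#`-prefixed trailer lines holding the thermodynamic block and the
#' quenching-mechanism classification.
#'
#' @param sv_fits List of [fit_stern_volmer()] results.
#' @param binding_fits List of [fit_binding_double_log()] results at the
#'   same temperatures.
#' @param thermo Optional `vanthoff_fit`.
#' @param mechanism Optional classification string.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_binding_report_csv <- function(sv_fits, binding_fits, thermo = NULL,
                                     mechanism = NULL, path) {
  rows <- do.call(rbind, Map(function(sv, bd) {
    data.frame(temperature_C = sv$temperature_c, ksv_per_M = sv$k_sv,
               kq_per_M_s = sv$k_q, kb_per_M = bd$k_b, n_apparent = bd$n,
               r2_sv = sv$r_squared, r2_binding = bd$r_squared)
  }, sv_fits, binding_fits))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  con <- file(path, open = "a")
  on.exit(close(con))
  if (!is.null(thermo)) {
    writeLines(sprintf("# dH_kJ_mol=%.10g", thermo$delta_h), con)
    writeLines(sprintf("# dS_J_mol_K=%.10g", thermo$delta_s), con)
    for (i in seq_along(thermo$temperatures_k))
      writeLines(sprintf("# dG_kJ_mol@%gK=%.10g", thermo$temperatures_k[i],
                         thermo$delta_g[i]), con)
  }
  if (!is.null(mechanism))
    writeLines(sprintf("# mechanism=%s", mechanism), con)
  invisible(path)
}
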