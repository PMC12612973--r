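#' Consolidated analysis report across assays
#'
#' Runs every analysis stage for which input is supplied and collects
#' the results into one machine-readable bundle: replicate kinetic
#' constants with mean/SD, Stern-Volmer / binding / Van't Hoff tables
#' with the quenching-mechanism call, endpoint percent inhibition, IC50,
#' and DLS sizes.  Blocks whose inputs are absent are simply omitted.
#' A provenance block records the seed, the configuration and the
#' package version so a rerun with identical inputs reproduces the
#' report byte for byte.
#'
#' @param traces Optional list of normalized [kinetic_trace()] objects
#'   (one compound's replicates).
#' @param titrations Optional list of [quench_titration()] objects at
#'   two or more temperatures.
#' @param dose_response Optional data frame with `dose_uM`, `response`.
#' @param endpoint_signals Optional named list
#'   `list(sample = , control = )` of blank-corrected endpoint signals.
#' @param dls Optional list with elements `distribution`
#'   ([size_distribution()]) and/or `curve` ([autocorrelation_curve()]).
#' @param config An [aggrekit_config()].
#' @param seed Seed recorded in provenance (and used nowhere else: the
#'   analyses are deterministic).
#' @return A list of class `"aggrekit_report"`.
#' @export
full_report <- function(traces = NULL, titrations = NULL,
                        dose_response = NULL, endpoint_signals = NULL,
                        dls = NULL, config = aggrekit_config(),
                        seed = NULL) {
  if (is.null(traces) && is.null(titrations) && is.null(dose_response) &&
      is.null(endpoint_signals) && is.null(dls))
    .validation_error("at least one assay input must be supplied")
  report <- list()

  if (!is.null(traces)) {
    grp <- fit_aggregation_replicates(traces, a = config$peptide_conc_molar,
                                      threshold_fractions =
                                        config$threshold_fractions)
    report$kinetics <- grp$table
  }

  if (!is.null(titrations)) {
    temps <- vapply(titrations, function(x) x$temperature_c, numeric(1))
    if (anyDuplicated(temps))
      .validation_error("duplicate temperatures across titration inputs")
    sv <- lapply(titrations, fit_stern_volmer, tau0 = config$tau0_s)
    bd <- lapply(titrations, fit_binding_double_log)
    vh <- if (length(titrations) >= 2)
      fit_vant_hoff(temps, vapply(bd, function(b) b$k_b, numeric(1)),
                    celsius = TRUE,
                    kelvin_offset = config$thermo_kelvin_offset)
    else NULL
    t_k <- temps + config$thermo_kelvin_offset
    report$binding <- data.frame(
      temperature_C = temps,
      ksv_per_M = vapply(sv, function(x) x$k_sv, numeric(1)),
      kq_per_M_s = vapply(sv, function(x) x$k_q, numeric(1)),
      kb_per_M = vapply(bd, function(x) x$k_b, numeric(1)),
      n_apparent = vapply(bd, function(x) x$n, numeric(1)),
      r2_sv = vapply(sv, function(x) x$r_squared, numeric(1)),
      r2_binding = vapply(bd, function(x) x$r_squared, numeric(1)),
      dG_from_kb_kJ_mol = gibbs_from_kb(
        vapply(bd, function(x) x$k_b, numeric(1)), t_k))
    report$mechanism <- if (length(sv) >= 2) classify_quenching(sv)
                        else "indeterminate"
    if (!is.null(vh)) {
      report$thermo <- list(dH_kJ_mol = vh$delta_h,
                            dS_J_mol_K = vh$delta_s,
                            dG_kJ_mol = as.list(vh$delta_g),
                            r_squared = vh$r_squared)
    }
  }

  if (!is.null(endpoint_signals)) {
    report$percent_inhibition <- percent_inhibition(
      endpoint_signals$sample, endpoint_signals$control)
  }

  if (!is.null(dose_response)) {
    ic <- fit_ic50(dose_response$dose_uM, dose_response$response)
    report$ic50 <- list(ic50_uM = ic$ic50, hill = ic$hill, top = ic$top,
                        bottom = ic$bottom, r_squared = ic$r_squared)
  }

  if (!is.null(dls)) {
    blk <- list()
    if (!is.null(dls$curve)) {
      cm <- fit_cumulant(dls$curve)
      blk$cumulant <- list(diffusion_m2_s = cm$diffusion_m2_s,
                           rh_nm = cm$rh_nm, pdi = cm$pdi)
    }
    if (!is.null(dls$distribution)) {
      blk$mean_rh_nm <- intensity_weighted_mean_rh(dls$distribution)
    }
    report$dls <- blk
  }

  report$provenance <- list(
    package = "aggrekit",
    version = as.character(utils::packageVersion("aggrekit")),
    seed = seed,
    config = unclass(config))
  class(report) <- "aggrekit_report"
  report
}

#' @export
print.aggrekit_report <- function(x, ...) {
  cat("== aggrekit analysis report ==\n")
  if (!is.null(x$kinetics)) {
    cat("\n-- Aggregation kinetics (per replicate + mean/sd) --\n")
    print(x$kinetics, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$binding)) {
    cat("\n-- Quenching & binding --\n")
    print(x$binding, digits = 4, row.names = FALSE)
    cat(sprintf("mechanism: %s\n", x$mechanism))
  }
  if (!is.null(x$thermo)) {
    cat(sprintf("thermo: dH = %.2f kJ/mol, dS = %.2f J/(mol K)\n",
                x$thermo$dH_kJ_mol, x$thermo$dS_J_mol_K))
    for (nm in names(x$thermo$dG_kJ_mol))
      cat(sprintf("  dG(%s K) = %.2f kJ/mol\n", nm, x$thermo$dG_kJ_mol[[nm]]))
  }
  if (!is.null(x$percent_inhibition))
    cat(sprintf("\npercent inhibition: %.1f%%\n", x$percent_inhibition))
  if (!is.null(x$ic50))
    cat(sprintf("\nIC50 = %.3g uM (hill %.3g, R^2 %.4f)\n",
                x$ic50$ic50_uM, x$ic50$hill, x$ic50$r_squared))
  if (!is.null(x$dls)) {
    cat("\n-- DLS --\n")
    if (!is.null(x$dls$cumulant))
      cat(sprintf("cumulant: R_h = %.4g nm, PDI = %.3g\n",
                  x$dls$cumulant$rh_nm, max(x$dls$cumulant$pdi, 0)))
    if (!is.null(x$dls$mean_rh_nm))
      cat(sprintf("intensity-weighted mean R_h = %.4g nm\n",
                  x$dls$mean_rh_nm))
  }
  invisible(x)
}

#' Write a report to JSON
#'
#' Full-precision JSON serialization of an [full_report()] bundle.
#'
#' @param report An `aggrekit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "aggrekit_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
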