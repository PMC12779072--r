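# File-in/file-out pipeline runners: thin orchestration over the module
# functions, mirroring the four report layouts (attenuation table, buildup
# table, docking/MM-PBSA report, MIC statistics). Each runner returns its
# result invisibly and optionally writes CSV; logging goes to stderr so
# results stay pipeline-composable. Output files are written atomically
# (temp file + rename) so a failure never leaves a partial file.

.write_csv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_csv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

.log_msg <- function(...) message("[shieldbio] ", ...)

.as_mev <- function(energies, unit = c("MeV", "keV")) {
  unit <- match.arg(unit)
  if (any(!is.finite(energies)) || any(energies <= 0)) {
    stop("energies must be positive and finite")
  }
  if (unit == "keV") energies / 1000 else energies
}

#' Run the attenuation pipeline
#'
#' Reads a compound file and a cross-section file, computes the
#' MAC/LAC/HVL/MFP profile at the requested energies and (optionally)
#' writes a flat report CSV with columns
#' `compound,source,energy_keV,mac_cm2_g,lac_cm1,hvl_cm,mfp_cm`.
#' Compounds without densities get MAC-only rows (a warning is logged).
#'
#' @param compounds_file CSV of compounds (see [read_compounds()]) or a
#'   compound data frame.
#' @param xs_file Cross-section CSV (see [read_xs_table()]) or a table.
#' @param energies Photon energies.
#' @param unit `"MeV"` (default) or `"keV"`.
#' @param out Optional output CSV path.
#' @param source Label for the report's `source` column (default
#'   `"computed"`).
#' @return The report tibble, invisibly.
#' @export
run_attenuate <- function(compounds_file, xs_file, energies,
                          unit = c("MeV", "keV"), out = NULL,
                          source = "computed") {
  unit <- match.arg(unit)
  compounds <- if (is.data.frame(compounds_file)) compounds_file else
    read_compounds(compounds_file)
  if (nrow(compounds) == 0L) stop("compound table is empty")
  xs <- if (is.data.frame(xs_file)) validate_xs_table(xs_file) else
    read_xs_table(xs_file)
  e_mev <- .as_mev(energies, unit)
  prof <- attenuation_profile(compounds, xs, e_mev)
  if ("density_g_cm3" %in% names(compounds) &&
      any(is.na(compounds$density_g_cm3))) {
    .log_msg("no density for compound(s): ",
             paste(compounds$id[is.na(compounds$density_g_cm3)], collapse = ", "),
             " — LAC/HVL/MFP omitted for those rows")
  }
  report <- tibble::tibble(
    compound = prof$id, source = source,
    energy_keV = prof$energy_MeV * 1000,
    mac_cm2_g = prof$mac_cm2_g, lac_cm1 = prof$lac_cm1,
    hvl_cm = prof$hvl_cm, mfp_cm = prof$mfp_cm
  )
  if (!is.null(out)) .write_csv_atomic(report, out)
  invisible(report)
}

#' Run the buildup pipeline
#'
#' Computes Zeq and G-P buildup factors for each compound over an energy
#' grid at the requested penetration depths, and optionally writes
#' `compound,kind,energy_MeV,zeq,depth_mfp,B`.
#'
#' @param compounds_file Compound CSV or data frame.
#' @param xs_file Cross-section CSV or table (both channels).
#' @param gp_file G-P parameter CSV or table.
#' @param energies Photon energies, MeV; `NULL` uses the G-P grid within
#'   cross-section coverage.
#' @param depths Penetration depths, mfp (default 10, 20, 40; must lie
#'   within the 40-mfp G-P validity domain).
#' @param kind `"EBF"` or `"EABF"`.
#' @param out Optional output CSV path.
#' @return The buildup tibble, invisibly.
#' @export
run_buildup <- function(compounds_file, xs_file, gp_file, energies = NULL,
                        depths = c(10, 20, 40), kind = c("EBF", "EABF"),
                        out = NULL) {
  kind <- match.arg(kind)
  compounds <- if (is.data.frame(compounds_file)) compounds_file else
    read_compounds(compounds_file)
  xs <- if (is.data.frame(xs_file)) validate_xs_table(xs_file) else
    read_xs_table(xs_file)
  gp <- if (is.data.frame(gp_file)) validate_gp_table(gp_file) else
    read_gp_table(gp_file)
  curve <- buildup_curve(compounds, xs, gp, energies, depths, kind)
  report <- tibble::tibble(
    compound = curve$id, kind = curve$kind, energy_MeV = curve$energy_MeV,
    zeq = curve$zeq, depth_mfp = curve$depth_mfp, B = curve$B
  )
  if (!is.null(out)) .write_csv_atomic(report, out)
  invisible(report)
}

#' Run the docking / MM-PBSA report
#'
#' Annotates a docking table with computed inhibition constants and the
#' best-complex flag; aggregates MM/PBSA components when supplied.
#' Engine-printed Ki values that disagree with the conversion beyond the
#' tolerance are flagged (and logged), never overwritten; with
#' `strict = TRUE` they abort the run.
#'
#' @param docking_file Docking CSV or data frame.
#' @param mmpbsa_file Optional MM/PBSA CSV or data frame.
#' @param out Optional output CSV path for the docking report.
#' @param out_mmpbsa Optional output CSV path for the MM/PBSA totals.
#' @param strict Abort on flagged inconsistencies (default `FALSE`).
#' @param tol Printed-Ki consistency tolerance (default 2%).
#' @return A list with `docking` (annotated tibble) and `mmpbsa` (totals
#'   tibble or `NULL`), invisibly.
#' @export
run_dock_report <- function(docking_file, mmpbsa_file = NULL, out = NULL,
                            out_mmpbsa = NULL, strict = FALSE, tol = 0.02) {
  docking <- if (is.data.frame(docking_file)) docking_file else
    read_docking_table(docking_file)
  if (nrow(docking) == 0L) stop("empty docking table")
  rep_dock <- dock_report(docking, tol = tol)
  if ("ki_consistent" %in% names(rep_dock) && any(!rep_dock$ki_consistent)) {
    bad <- rep_dock[!rep_dock$ki_consistent, ]
    msg <- paste0(bad$ligand, "-", bad$receptor_pdb, collapse = ", ")
    if (strict) stop("printed Ki inconsistent with conversion for: ", msg)
    .log_msg("printed Ki inconsistent with conversion for: ", msg)
  }
  totals <- NULL
  if (!is.null(mmpbsa_file)) {
    comp <- if (is.data.frame(mmpbsa_file)) mmpbsa_file else
      read_mmpbsa(mmpbsa_file)
    totals <- mmpbsa_total(comp)
    if (!is.null(out_mmpbsa)) .write_csv_atomic(totals, out_mmpbsa)
  }
  if (!is.null(out)) .write_csv_atomic(rep_dock, out)
  invisible(list(docking = rep_dock, mmpbsa = totals))
}

#' Run the MIC statistics pipeline
#'
#' Ladder validation, per-organism best compounds, one-way ANOVA and Tukey
#' HSD pairwise comparisons on a MIC matrix.
#'
#' @param mic_file MIC CSV (see [read_mic_matrix()]) or long data frame.
#' @param ladder Concentration ladder (default the packaged
#'   78-1250 ug/mL two-fold series).
#' @param scale `"log2"` (default) or `"raw"` response scale.
#' @param alpha Significance level.
#' @param out_prefix Optional path prefix; writes
#'   `<prefix>_violations.csv`, `<prefix>_best.csv`, `<prefix>_anova.csv`,
#'   `<prefix>_tukey.csv`.
#' @return A list with `violations`, `summary`, `anova`, `tukey`,
#'   invisibly.
#' @export
run_mic <- function(mic_file, ladder = dilution_ladder(c(78, 156, 312, 625, 1250)),
                    scale = c("log2", "raw"), alpha = 0.05,
                    out_prefix = NULL) {
  scale <- match.arg(scale)
  mic <- if (is.data.frame(mic_file)) mic_file else read_mic_matrix(mic_file)
  if (all(is.na(mic$mic))) stop("MIC matrix has no tested values")
  violations <- validate_mic_series(mic, ladder)
  if (nrow(violations) > 0L) {
    .log_msg(nrow(violations), " MIC value(s) off the dilution ladder")
  }
  summ <- mic_summary(mic)
  cmp <- mic_compare(mic, scale = scale, alpha = alpha)
  if (!is.null(out_prefix)) {
    .write_csv_atomic(violations, paste0(out_prefix, "_violations.csv"))
    .write_csv_atomic(summ$best_by_organism, paste0(out_prefix, "_best.csv"))
    .write_csv_atomic(tidy(cmp$anova), paste0(out_prefix, "_anova.csv"))
    tk <- cmp$tukey
    tk$pair <- paste(tk$group1, tk$group2, sep = "-")
    .write_csv_atomic(
      tk[, c("pair", "mean_diff", "q", "adj_p", "significant")],
      paste0(out_prefix, "_tukey.csv")
    )
  }
  invisible(list(violations = violations, summary = summ,
                 anova = cmp$anova, tukey = cmp$tukey))
}

#' Generate the full synthetic input set
#'
#' Emits the four synthetic tables (cross sections, G-P parameters,
#' docking, MIC) for one root seed, plus a JSON ground-truth sidecar with
#' the generator coefficients and true effects.
#'
#' @param seed Root seed.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param config Optional [synthetic_config()]; its seed is overridden by
#'   `seed` when both are given.
#' @return A list with the four tables and the ground-truth list,
#'   invisibly.
#' @export
run_simulate <- function(seed = 1L, out_dir = NULL, config = NULL) {
  if (is.null(config)) config <- synthetic_config(seed = seed)
  else config$seed <- as.integer(seed)
  xs <- gen_xs_table(config)
  gp <- gen_gp_table(config)
  dock <- gen_docking_table(config)
  mic <- gen_mic_matrix(config)
  truth <- list(
    seed = config$seed,
    xs_closed_form = attr(xs, "closed_form"),
    docking_true_dg = attr(dock, "true_dg"),
    mic_truth = attr(mic, "truth")[c("compound_effects", "baseline")]
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_csv_atomic(xs, file.path(out_dir, "synthetic_xs.csv"))
    .write_csv_atomic(gp, file.path(out_dir, "synthetic_gp.csv"))
    .write_csv_atomic(dock, file.path(out_dir, "synthetic_docking.csv"))
    .write_csv_atomic(mic, file.path(out_dir, "synthetic_mic.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(xs = xs, gp = gp, docking = dock, mic = mic, truth = truth))
}
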