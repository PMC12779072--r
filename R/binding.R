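# Docking thermodynamics post-processing: binding free energy <-> inhibition
# constant conversion, complex ranking, MM/PBSA component aggregation and
# per-residue contribution summaries.
#
# Docking engines report the predicted inhibition constant alongside the
# binding free energy through Ki = exp(dG / RT); the constants below
# (R = 1.98722e-3 kcal/mol/K, T = 298.15 K) are the docking convention.

#' @rdname ki_from_binding_energy
#' @format NULL
#' @export
GAS_CONSTANT_KCAL <- 1.98722e-3  # kcal mol^-1 K^-1

#' Inhibition constant from binding free energy
#'
#' `Ki = exp(dG / (R T))` in molar units, with the gas constant in
#' kcal/mol/K and T in kelvin. The default temperature 298.15 K together
#' with R = 1.98722e-3 kcal/mol/K is the convention under which docking
#' engines print Ki next to the binding energy.
#'
#' @param dg Binding free energies, kcal/mol (negative = favorable).
#' @param temperature Absolute temperature, K.
#' @param gas_constant Gas constant, kcal/mol/K.
#' @return Inhibition constants, molar.
#' @export
#' @examples
#' ki_from_binding_energy(-10.90) * 1e9  # nM
ki_from_binding_energy <- function(dg, temperature = 298.15,
                                   gas_constant = GAS_CONSTANT_KCAL) {
  if (any(!is.finite(dg))) stop("`dg` must be finite")
  stopifnot(temperature > 0, gas_constant > 0)
  exp(dg / (gas_constant * temperature))
}

#' Binding free energy from inhibition constant
#'
#' Inverse of [ki_from_binding_energy()]: `dG = R T ln(Ki)`.
#'
#' @param ki Inhibition constants, molar (> 0).
#' @inheritParams ki_from_binding_energy
#' @return Binding free energies, kcal/mol.
#' @export
binding_energy_from_ki <- function(ki, temperature = 298.15,
                                   gas_constant = GAS_CONSTANT_KCAL) {
  if (any(!is.finite(ki)) || any(ki <= 0)) stop("`ki` must be positive and finite")
  gas_constant * temperature * log(ki)
}

#' Format an inhibition constant with its natural unit
#'
#' Scales to nM below 1 uM, uM below 1 mM, mM below 1 M, else M; two
#' decimals, matching the usual docking-report style.
#'
#' @param ki Inhibition constants, molar (> 0).
#' @return Character vector like `"10.19 nM"`.
#' @export
#' @examples
#' format_ki(c(1.019e-8, 3.12e-6, 1))
format_ki <- function(ki) {
  if (any(!is.finite(ki)) || any(ki <= 0)) stop("`ki` must be positive and finite")
  vapply(ki, function(k) {
    if (k < 1e-6) sprintf("%.2f nM", k * 1e9)
    else if (k < 1e-3) sprintf("%.2f μM", k * 1e6)
    else if (k < 1) sprintf("%.2f mM", k * 1e3)
    else sprintf("%.2f M", k)
  }, character(1))
}

.ki_in_unit <- function(ki, unit) {
  scale <- c("nM" = 1e9, "μM" = 1e6, "uM" = 1e6, "mM" = 1e3, "M" = 1)
  if (!unit %in% names(scale)) stop("unknown Ki unit: ", unit)
  ki * scale[[unit]]
}

#' Read a docking result file
#'
#' CSV with header
#' `ligand,receptor_pdb,binding_energy_kcal_mol,n_hbonds,hbond_residues,vdw_residues`
#' (residue lists semicolon-separated). Optional `ki_value`/`ki_unit`
#' columns carry an engine-printed inhibition constant, kept for
#' consistency checking but never overwritten.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per ligand-receptor complex.
#' @export
read_docking_table <- function(path) {
  x <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    ligand = readr::col_character(),
    receptor_pdb = readr::col_character(),
    binding_energy_kcal_mol = readr::col_double(),
    n_hbonds = readr::col_integer(),
    .default = readr::col_character()
  ))
  need <- c("ligand", "receptor_pdb", "binding_energy_kcal_mol")
  if (!all(need %in% names(x))) {
    stop("docking table must have columns: ", paste(need, collapse = ", "))
  }
  if ("ki_value" %in% names(x)) x$ki_value <- as.numeric(x$ki_value)
  if ("n_hbonds" %in% names(x) && any(stats::na.omit(x$n_hbonds) < 0)) {
    stop("`n_hbonds` must be non-negative")
  }
  x
}

#' Annotate a docking table with inhibition constants
#'
#' Data-frame-first: adds the computed `ki_M` and a formatted `ki_label`,
#' flags the best (most negative binding energy) complex, and, when the
#' table carries an engine-printed `ki_value`/`ki_unit` pair, a
#' `ki_consistent` flag marking whether the printed value agrees with the
#' conversion within `tol` (printed values are flagged, never overwritten).
#'
#' @param docking A docking table (see [read_docking_table()]).
#' @param tol Relative tolerance for the printed-Ki consistency check;
#'   default 2%, the slack implied by binding energies printed to two
#'   decimals.
#' @inheritParams ki_from_binding_energy
#' @return The input tibble with columns `ki_M`, `ki_label`, `best` (and
#'   `ki_consistent` when printed values are present) appended.
#' @export
dock_report <- function(docking, tol = 0.02, temperature = 298.15,
                        gas_constant = GAS_CONSTANT_KCAL) {
  stopifnot(is.data.frame(docking),
            all(c("ligand", "receptor_pdb", "binding_energy_kcal_mol") %in% names(docking)))
  if (nrow(docking) == 0L) stop("empty docking table")
  out <- tibble::as_tibble(docking)
  out$ki_M <- ki_from_binding_energy(out$binding_energy_kcal_mol,
                                     temperature, gas_constant)
  out$ki_label <- format_ki(out$ki_M)
  best <- select_best_complex(out)
  out$best <- out$ligand == best$ligand & out$receptor_pdb == best$receptor_pdb
  if (all(c("ki_value", "ki_unit") %in% names(out))) {
    printed <- purrr::map2_dbl(out$ki_M, out$ki_unit, .ki_in_unit)
    out$ki_consistent <- abs(printed - as.numeric(out$ki_value)) /
      printed <= tol
  }
  out
}

#' Best-binding complex
#'
#' The record with the most negative binding free energy; ties broken
#' deterministically by (ligand, receptor) lexicographic order.
#'
#' @param docking A docking table.
#' @return A one-row tibble.
#' @export
select_best_complex <- function(docking) {
  stopifnot(is.data.frame(docking))
  if (nrow(docking) == 0L) stop("empty docking table")
  ord <- order(docking$binding_energy_kcal_mol, docking$ligand, docking$receptor_pdb)
  tibble::as_tibble(docking[ord[1], , drop = FALSE])
}

#' Read an MM/PBSA component file
#'
#' CSV with header `complex,term,value_kcal_mol,sd`, term in
#' `{vdw, ele, polar, nonpolar}`; `sd` may be empty.
#'
#' @param path Path to the CSV file.
#' @return A tibble in long form.
#' @export
read_mmpbsa <- function(path) {
  x <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    complex = readr::col_character(), term = readr::col_character(),
    value_kcal_mol = readr::col_double(), sd = readr::col_double()
  ))
  bad <- setdiff(unique(x$term), c("vdw", "ele", "polar", "nonpolar"))
  if (length(bad) > 0L) stop("unknown MM/PBSA term(s): ", paste(bad, collapse = ", "))
  x
}

#' Aggregate MM/PBSA components into a total binding free energy
#'
#' Sums the four end-point components (van der Waals, electrostatic, polar
#' solvation, nonpolar solvation) per complex. When standard deviations are
#' supplied the reported `sd_total` is the root-sum-of-squares propagation
#' (a reporting convenience; component correlations are ignored).
#'
#' @param components Long tibble with columns `complex`, `term`,
#'   `value_kcal_mol` and optionally `sd` (see [read_mmpbsa()]).
#' @return A tibble with one row per complex: the four components, `total`
#'   and `sd_total` (NA when any component sd is missing).
#' @export
#' @examples
#' mmpbsa_total(tibble::tibble(
#'   complex = "2VF5-2d", term = c("vdw", "ele", "polar", "nonpolar"),
#'   value_kcal_mol = c(-42.73, -22.59, 41.99, -3.98)
#' ))
mmpbsa_total <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("complex", "term", "value_kcal_mol") %in% names(components)))
  need <- c("vdw", "ele", "polar", "nonpolar")
  if (!"sd" %in% names(components)) components$sd <- NA_real_
  purrr::map_dfr(split(components, components$complex), function(g) {
    missing <- setdiff(need, g$term)
    if (length(missing) > 0L) {
      stop("complex ", g$complex[1], " missing MM/PBSA term(s): ",
           paste(missing, collapse = ", "))
    }
    if (any(duplicated(g$term))) stop("duplicated MM/PBSA terms for ", g$complex[1])
    v <- stats::setNames(g$value_kcal_mol, g$term)
    if (any(!is.finite(v))) stop("non-finite MM/PBSA component for ", g$complex[1])
    s <- stats::setNames(g$sd, g$term)
    tibble::tibble(
      complex = g$complex[1],
      vdw = v[["vdw"]], ele = v[["ele"]],
      polar = v[["polar"]], nonpolar = v[["nonpolar"]],
      total = sum(v[need]),
      sd_total = if (any(is.na(s[need]))) NA_real_ else sqrt(sum(s[need]^2))
    )
  })
}

#' Rank per-residue binding energy contributions
#'
#' Sorts residues by contribution, most stabilizing (most negative) first;
#' ties broken by residue label for a stable ordering.
#'
#' @param residues Named numeric vector or data frame with columns
#'   `residue`, `energy_kcal_mol`.
#' @param top_n Keep only the `top_n` most stabilizing residues
#'   (default all).
#' @return A tibble with columns `rank`, `residue`, `energy_kcal_mol`.
#' @export
#' @examples
#' residue_contribution_summary(c(ARG311 = -21.07, GLU315 = -6.0, TRP313 = -5.4))
residue_contribution_summary <- function(residues, top_n = Inf) {
  if (is.data.frame(residues)) {
    stopifnot(all(c("residue", "energy_kcal_mol") %in% names(residues)))
    res <- residues$residue; e <- residues$energy_kcal_mol
  } else {
    res <- names(residues); e <- as.numeric(residues)
  }
  if (length(e) == 0L) stop("empty residue contribution map")
  ord <- order(e, res)
  n <- min(length(e), top_n)
  tibble::tibble(rank = seq_len(n), residue = res[ord][seq_len(n)],
                 energy_kcal_mol = e[ord][seq_len(n)])
}
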