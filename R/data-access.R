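# Accessors for the packaged reference tables: the six bis-piperazine
# Schiff-base candidates (2a-2f), their published linear attenuation
# coefficients, docking and MM/PBSA results, MIC matrix, and the H/C/N/O
# elemental cross-section reference table.

#' Path to a packaged example file
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' shieldbio_example()
shieldbio_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "shieldbio")))
  }
  path <- system.file("extdata", file, package = "shieldbio")
  if (!nzchar(path)) stop("no packaged file named ", file)
  path
}

#' Packaged compound definitions (2a-2f)
#'
#' The six bis-piperazine Schiff-base candidates as molecular formulas.
#' Densities are not published for these compounds and are left `NA`; use
#' [infer_density()] against an anchor linear attenuation coefficient from
#' [bp_lac()] when density-dependent quantities are needed.
#'
#' @return A tibble with columns `id`, `formula`, `density_g_cm3`.
#' @export
bp_compounds <- function() {
  read_compounds(shieldbio_example("compounds_2a2f.csv"))
}

#' Packaged published linear attenuation coefficients
#'
#' Published LAC values (cm^-1) for compounds 2a-2f at 80, 120, 662, 1173
#' and 1332 keV from three calculation routes (XCOM, Phy-X, GATE).
#'
#' @return A tibble with columns `compound`, `source`, `energy_keV`,
#'   `lac_cm1`.
#' @export
bp_lac <- function() {
  readr::read_csv(shieldbio_example("lac_reference.csv"), comment = "#",
                  col_types = readr::cols(
                    compound = readr::col_character(),
                    source = readr::col_character(),
                    energy_keV = readr::col_double(),
                    lac_cm1 = readr::col_double()
                  ))
}

#' Packaged docking results for ligands 2d and 2f
#'
#' Binding free energies, engine-printed inhibition constants, hydrogen
#' bond counts and interacting residue lists for ligands 2d and 2f against
#' four antibacterial target proteins (beta-ketoacyl-ACP synthase II 1HNJ,
#' GlcN-6-P synthase 2VF5, DNA gyrase A 5CDN, DNA gyrase B 5MMN).
#'
#' @return A docking tibble (see [read_docking_table()]).
#' @export
bp_docking <- function() {
  read_docking_table(shieldbio_example("docking_2d2f.csv"))
}

#' Packaged MM/PBSA components for the 2VF5-2d complex
#'
#' @return A long tibble (see [read_mmpbsa()]).
#' @export
bp_mmpbsa <- function() {
  read_mmpbsa(shieldbio_example("mmpbsa_2vf5_2d.csv"))
}

#' Packaged MIC matrix for compounds 2a-2f
#'
#' Broth-microdilution MICs (ug/mL) of the six candidates against eight
#' bacterial strains and one fungal species, on the two-fold ladder
#' 78-1250 ug/mL.
#'
#' @return A long MIC tibble (see [read_mic_matrix()]).
#' @export
bp_mic <- function() {
  read_mic_matrix(shieldbio_example("mic_2a2f.csv"))
}

#' Packaged H/C/N/O cross-section reference table
#'
#' Total and Compton (incoherent) mass attenuation coefficients for
#' hydrogen, carbon, nitrogen and oxygen on a 26-point grid spanning
#' 0.015-15 MeV. Totals follow the standard tabulation for these elements;
#' the incoherent channel is computed from the Klein-Nishina per-electron
#' cross section scaled by N_A Z/A (see the file header for provenance and
#' the methods vignette for the low-energy caveat).
#'
#' @return A validated cross-section tibble.
#' @export
xs_reference <- function() {
  read_xs_table(shieldbio_example("xs_hcno_reference.csv"))
}

#' Packaged example G-P parameter table (synthetic)
#'
#' A smooth synthetic G-P parameter table over Z = 4-26 and 0.015-15 MeV,
#' for demonstrations and pipeline tests. It is *not* the standard
#' reference tabulation; real buildup studies should supply their own
#' table via [read_gp_table()].
#'
#' @return A validated G-P tibble.
#' @export
gp_example <- function() {
  read_gp_table(shieldbio_example("gp_synthetic_example.csv"))
}
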