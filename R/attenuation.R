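# Photon attenuation: elemental cross-section interpolation, mixture-rule
# mass attenuation coefficients, and the derived linear attenuation
# coefficient, half-value layer and mean free path.
#
# The mixture rule gives the compound mass attenuation coefficient as
#   (mu/rho)_compound(E) = sum_i W_i (mu/rho)_i(E)
# with W_i the elemental weight fractions. Elemental tables are evaluated
# off-grid by log-log linear interpolation, the standard choice for photon
# cross sections (and exact when the underlying curve is a power law).

#' Validate a cross-section table
#'
#' Checks the structural invariants of an elemental cross-section table:
#' strictly increasing energy grid per element, strictly positive
#' coefficients, and Compton (incoherent) partial coefficients never
#' exceeding the totals.
#'
#' @param xs A data frame with columns `element`, `Z`, `energy_MeV`,
#'   `total_mu_rho_cm2_g`, `compton_mu_rho_cm2_g`.
#' @return `xs`, invisibly, if valid; otherwise an error.
#' @export
validate_xs_table <- function(xs) {
  need <- c("element", "Z", "energy_MeV", "total_mu_rho_cm2_g", "compton_mu_rho_cm2_g")
  if (!is.data.frame(xs) || !all(need %in% names(xs))) {
    stop("cross-section table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(xs$total_mu_rho_cm2_g <= 0) || any(xs$compton_mu_rho_cm2_g <= 0)) {
    stop("cross-section coefficients must be strictly positive")
  }
  if (any(xs$compton_mu_rho_cm2_g > xs$total_mu_rho_cm2_g + 1e-12)) {
    stop("Compton partial coefficient exceeds total coefficient")
  }
  for (el in unique(xs$element)) {
    e <- xs$energy_MeV[xs$element == el]
    if (any(diff(e) <= 0)) stop("energy grid for element ", el, " is not strictly increasing")
  }
  invisible(xs)
}

#' Read an elemental cross-section file
#'
#' CSV with header `element,Z,energy_MeV,total_mu_rho_cm2_g,compton_mu_rho_cm2_g`;
#' lines starting with `#` are comments. The table is validated on read.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_xs_table <- function(path) {
  xs <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    element = readr::col_character(),
    Z = readr::col_integer(),
    energy_MeV = readr::col_double(),
    total_mu_rho_cm2_g = readr::col_double(),
    compton_mu_rho_cm2_g = readr::col_double()
  ))
  validate_xs_table(xs)
  xs
}

#' Interpolate an elemental cross section
#'
#' Log-log linear interpolation of a tabulated elemental mass attenuation
#' coefficient at arbitrary energies within the grid. Exact at grid points
#' and on power-law tables; no extrapolation is performed (silent
#' extrapolation of cross sections is a known error source).
#'
#' @param xs A cross-section table (see [read_xs_table()]).
#' @param element Element symbol to look up.
#' @param energy Photon energies, MeV (vectorized).
#' @param channel `"total"` or `"compton"` (incoherent partial).
#' @return Interpolated mass attenuation coefficients, cm^2/g.
#' @export
interpolate_xs <- function(xs, element, energy, channel = c("total", "compton")) {
  channel <- match.arg(channel)
  tab <- xs[xs$element == element, ]
  if (nrow(tab) == 0L) stop("element not in cross-section table: ", element)
  if (any(!is.finite(energy)) || any(energy <= 0)) stop("energies must be positive and finite")
  lo <- min(tab$energy_MeV); hi <- max(tab$energy_MeV)
  if (any(energy < lo | energy > hi)) {
    stop(sprintf("energy outside tabulated grid [%g, %g] MeV for element %s", lo, hi, element))
  }
  col <- if (channel == "total") "total_mu_rho_cm2_g" else "compton_mu_rho_cm2_g"
  exp(stats::approx(log(tab$energy_MeV), log(tab[[col]]), xout = log(energy),
                    ties = "ordered")$y)
}

#' Mixture-rule mass attenuation coefficient
#'
#' Weight-fraction-weighted sum of interpolated elemental coefficients:
#' the compound MAC at each requested energy.
#'
#' @param xs Cross-section table.
#' @param formula Molecular formula string or named count vector.
#' @param energy Photon energies, MeV (vectorized).
#' @param channel `"total"` or `"compton"`.
#' @param weights Optional atomic weight table.
#' @return Compound mass attenuation coefficients, cm^2/g.
#' @export
#' @examples
#' xs <- xs_reference()
#' mixture_mac(xs, "C30H44N6O2", 0.662)
mixture_mac <- function(xs, formula, energy, channel = c("total", "compton"),
                        weights = NULL) {
  channel <- match.arg(channel)
  counts <- if (is.character(formula)) parse_formula(formula, weights) else formula
  frac <- weight_fractions(counts, weights)
  missing <- setdiff(names(frac), unique(xs$element))
  if (length(missing) > 0L) {
    stop("element(s) absent from cross-section table: ", paste(missing, collapse = ", "))
  }
  terms <- vapply(names(frac), function(el) {
    frac[[el]] * interpolate_xs(xs, el, energy, channel)
  }, numeric(length(energy)))
  if (length(energy) == 1L) sum(terms) else rowSums(terms)
}

#' Linear attenuation coefficient
#'
#' LAC = MAC x density.
#'
#' @param mac Mass attenuation coefficient, cm^2/g.
#' @param density Mass density, g/cm^3.
#' @return Linear attenuation coefficient, cm^-1.
#' @export
linear_attenuation <- function(mac, density) {
  if (any(!is.finite(mac)) || any(mac <= 0)) stop("`mac` must be positive and finite")
  if (any(!is.finite(density)) || any(density <= 0)) stop("`density` must be positive and finite")
  mac * density
}

#' Half-value layer
#'
#' Thickness that halves the primary beam intensity: HVL = ln(2) / LAC.
#' The exact natural logarithm of 2 is used (the value 0.693 sometimes
#' quoted is a presentational rounding).
#'
#' @param lac Linear attenuation coefficient, cm^-1.
#' @return Half-value layer, cm.
#' @export
half_value_layer <- function(lac) {
  if (any(!is.finite(lac)) || any(lac <= 0)) stop("`lac` must be positive and finite")
  log(2) / lac
}

#' Mean free path
#'
#' Average distance a photon travels between interactions: MFP = 1 / LAC.
#'
#' @inheritParams half_value_layer
#' @return Mean free path, cm.
#' @export
mean_free_path <- function(lac) {
  if (any(!is.finite(lac)) || any(lac <= 0)) stop("`lac` must be positive and finite")
  1 / lac
}

#' Attenuation profile of a compound table
#'
#' Computes MAC (always) and LAC/HVL/MFP (when a density is available) for
#' each compound at each requested energy. Compounds without a density get
#' `NA` in the density-dependent columns.
#'
#' @param compounds A data frame with columns `id`, `formula`, and
#'   optionally `density_g_cm3`.
#' @param xs Cross-section table.
#' @param energies Photon energies, MeV.
#' @param weights Optional atomic weight table.
#' @return A tibble of class `attenuation_profile` with columns `id`,
#'   `formula`, `density_g_cm3`, `energy_MeV`, `mac_cm2_g`, `lac_cm1`,
#'   `hvl_cm`, `mfp_cm`.
#' @export
#' @examples
#' cmp <- tibble::tibble(id = "2a", formula = "C30H44N6O2", density_g_cm3 = 1.2)
#' attenuation_profile(cmp, xs_reference(), c(0.662, 1.173))
attenuation_profile <- function(compounds, xs, energies, weights = NULL) {
  stopifnot(is.data.frame(compounds), all(c("id", "formula") %in% names(compounds)))
  if (!"density_g_cm3" %in% names(compounds)) compounds$density_g_cm3 <- NA_real_
  out <- purrr::pmap_dfr(
    compounds[, c("id", "formula", "density_g_cm3")],
    function(id, formula, density_g_cm3) {
      mac <- mixture_mac(xs, formula, energies, "total", weights)
      if (!is.na(density_g_cm3)) {
        lac <- linear_attenuation(mac, density_g_cm3)
        hvl <- half_value_layer(lac)
        mfp <- mean_free_path(lac)
      } else {
        lac <- hvl <- mfp <- rep(NA_real_, length(energies))
      }
      tibble::tibble(
        id = id, formula = formula, density_g_cm3 = density_g_cm3,
        energy_MeV = energies, mac_cm2_g = mac,
        lac_cm1 = lac, hvl_cm = hvl, mfp_cm = mfp
      )
    }
  )
  class(out) <- c("attenuation_profile", class(out))
  out
}

#' Infer a mass density from an anchor measurement
#'
#' Back-solves density = LAC / MAC at a single anchor energy. Useful when a
#' published table prints linear attenuation coefficients but not the
#' densities behind them: the density recovered at one energy lets every
#' other energy be cross-validated.
#'
#' @param formula Molecular formula string or named counts.
#' @param xs Cross-section table.
#' @param anchor_energy Anchor photon energy, MeV.
#' @param anchor_lac Linear attenuation coefficient at the anchor, cm^-1.
#' @param weights Optional atomic weight table.
#' @return Inferred density, g/cm^3.
#' @export
infer_density <- function(formula, xs, anchor_energy, anchor_lac, weights = NULL) {
  if (!is.finite(anchor_lac) || anchor_lac <= 0) stop("`anchor_lac` must be positive")
  anchor_lac / mixture_mac(xs, formula, anchor_energy, "total", weights)
}
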