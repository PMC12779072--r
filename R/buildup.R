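# Equivalent atomic number and geometric-progression (G-P) buildup factors.
#
# Buildup factors correct the uncollided-beam estimate for scattered
# photons. The G-P representation parameterizes the buildup factor B at
# penetration depth x (in mean free paths) by five parameters (b, c, a,
# Xk, d):
#   K(E,x) = c x^a + d [tanh(x/Xk - 2) - tanh(-2)] / [1 - tanh(-2)]
#   B(E,x) = 1 + (b-1)(K^x - 1)/(K - 1)   (K != 1)
#   B(E,x) = 1 + (b-1) x                  (K  = 1)
# valid for x <= 40 mfp. Parameters for a compound are obtained at its
# equivalent atomic number Zeq, the single-element Z whose Compton-to-total
# attenuation ratio matches the compound's at the given energy:
#   Zeq = [Z1 (log R2 - log R) + Z2 (log R - log R1)] / (log R2 - log R1)
# with (Z1, R1), (Z2, R2) the bracketing tabulated entries.

#' Compton-to-total attenuation ratio of a compound
#'
#' The ratio of the mixture incoherent (Compton) MAC to the mixture total
#' MAC at a given energy; the quantity matched when computing the
#' equivalent atomic number.
#'
#' @param xs Cross-section table with both channels.
#' @param formula Molecular formula string or named counts.
#' @param energy Photon energies, MeV (vectorized).
#' @param weights Optional atomic weight table.
#' @return Ratios in (0, 1].
#' @export
compton_total_ratio <- function(xs, formula, energy, weights = NULL) {
  mixture_mac(xs, formula, energy, "compton", weights) /
    mixture_mac(xs, formula, energy, "total", weights)
}

#' Elemental Compton-to-total ratios at one energy
#'
#' @param xs Cross-section table.
#' @param energy A single photon energy, MeV.
#' @return A tibble with columns `element`, `Z`, `R`, sorted by `Z`.
#' @export
elemental_ratios <- function(xs, energy) {
  stopifnot(length(energy) == 1L)
  els <- unique(xs[, c("element", "Z")])
  els <- els[order(els$Z), ]
  R <- vapply(els$element, function(el) {
    interpolate_xs(xs, el, energy, "compton") / interpolate_xs(xs, el, energy, "total")
  }, numeric(1))
  tibble::tibble(element = els$element, Z = els$Z, R = unname(R))
}

#' Equivalent atomic number by log-ratio interpolation
#'
#' Given a compound's Compton-to-total ratio R and the elemental ratios at
#' the same energy, finds the two consecutive tabulated atomic numbers
#' whose ratios bracket R and interpolates
#' `Zeq = [Z1 (log R2 - log R) + Z2 (log R - log R1)] / (log R2 - log R1)`.
#' No clamping: an R outside the elemental span is an error, as is a
#' non-monotone ratio table (which would make the bracket ambiguous).
#'
#' @param R The compound's Compton-to-total ratio.
#' @param ratios A data frame with columns `Z` and `R` (e.g. from
#'   [elemental_ratios()]), one row per tabulated element.
#' @return A one-row tibble with columns `R`, `Z1`, `Z2`, `R1`, `R2`, `zeq`.
#' @export
equivalent_atomic_number <- function(R, ratios) {
  stopifnot(is.data.frame(ratios), all(c("Z", "R") %in% names(ratios)))
  ratios <- ratios[order(ratios$Z), ]
  rz <- ratios$R
  d <- diff(rz)
  if (!(all(d > 0) || all(d < 0))) {
    stop("elemental Compton/total ratios are not monotone in Z at this energy; ",
         "Zeq bracketing is ambiguous")
  }
  if (R < min(rz) || R > max(rz)) {
    stop(sprintf("ratio R = %.6g outside the elemental span [%.6g, %.6g]",
                 R, min(rz), max(rz)))
  }
  # exact hit on a tabulated entry
  hit <- which(abs(rz - R) < .Machine$double.eps * 8)
  if (length(hit) > 0L) {
    i <- hit[1]
    return(tibble::tibble(R = R, Z1 = ratios$Z[i], Z2 = ratios$Z[i],
                          R1 = rz[i], R2 = rz[i], zeq = as.numeric(ratios$Z[i])))
  }
  inside <- which((rz[-length(rz)] - R) * (rz[-1] - R) < 0)
  i <- inside[1]
  Z1 <- ratios$Z[i]; Z2 <- ratios$Z[i + 1]
  R1 <- rz[i]; R2 <- rz[i + 1]
  zeq <- (Z1 * (log(R2) - log(R)) + Z2 * (log(R) - log(R1))) / (log(R2) - log(R1))
  tibble::tibble(R = R, Z1 = Z1, Z2 = Z2, R1 = R1, R2 = R2, zeq = zeq)
}

#' Validate a G-P parameter table
#'
#' @param gp A data frame with columns `kind` (`"EBF"`/`"EABF"`), `Z`,
#'   `energy_MeV`, `b`, `c`, `a`, `Xk`, `d`.
#' @return `gp`, invisibly, if valid.
#' @export
validate_gp_table <- function(gp) {
  need <- c("kind", "Z", "energy_MeV", "b", "c", "a", "Xk", "d")
  if (!is.data.frame(gp) || !all(need %in% names(gp))) {
    stop("G-P table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(gp$kind %in% c("EBF", "EABF"))) stop("`kind` must be EBF or EABF")
  if (any(gp$b < 1)) stop("G-P parameter b must be >= 1")
  if (any(gp$Xk <= 0)) stop("G-P parameter Xk must be > 0")
  for (k in unique(gp$kind)) for (z in unique(gp$Z[gp$kind == k])) {
    e <- gp$energy_MeV[gp$kind == k & gp$Z == z]
    if (any(diff(e) <= 0)) {
      stop("energy grid not strictly increasing for kind ", k, ", Z ", z)
    }
  }
  invisible(gp)
}

#' Read a G-P parameter file
#'
#' CSV with header `kind,Z,energy_MeV,b,c,a,Xk,d`; `#` comments allowed.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_gp_table <- function(path) {
  gp <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    kind = readr::col_character(), Z = readr::col_integer(),
    energy_MeV = readr::col_double(), b = readr::col_double(),
    c = readr::col_double(), a = readr::col_double(),
    Xk = readr::col_double(), d = readr::col_double()
  ))
  validate_gp_table(gp)
  gp
}

.gp_interp_z <- function(tab, zeq) {
  # log-Z weighted interpolation of the five parameters between the
  # bracketing tabulated Z, mirroring the Zeq interpolation convention.
  zs <- sort(unique(tab$Z))
  if (zeq < min(zs) || zeq > max(zs)) {
    stop(sprintf("zeq = %.4g outside the G-P table Z range [%d, %d]",
                 zeq, min(zs), max(zs)))
  }
  pars <- c("b", "c", "a", "Xk", "d")
  if (any(abs(zs - zeq) < 1e-12)) {
    z0 <- zs[which.min(abs(zs - zeq))]
    row <- tab[tab$Z == z0, pars]
    return(as.list(row))
  }
  i <- findInterval(zeq, zs)
  Z1 <- zs[i]; Z2 <- zs[i + 1]
  w2 <- (log(zeq) - log(Z1)) / (log(Z2) - log(Z1))
  r1 <- tab[tab$Z == Z1, pars]; r2 <- tab[tab$Z == Z2, pars]
  as.list((1 - w2) * r1 + w2 * r2)
}

#' Interpolate G-P parameters at an equivalent atomic number
#'
#' For each of the five G-P parameters, interpolates between the bracketing
#' integer-Z table entries with logarithmic Z weights (the convention of
#' the buildup literature, mirroring the Zeq formula), then log-linearly in
#' energy when the requested energy falls between grid energies. Exact for
#' tabulated (Z, E).
#'
#' @param gp G-P parameter table.
#' @param zeq Equivalent atomic number (real-valued).
#' @param energy Photon energy, MeV.
#' @param kind `"EBF"` or `"EABF"`.
#' @return A one-row tibble with columns `b`, `c`, `a`, `Xk`, `d`.
#' @export
interpolate_gp_parameters <- function(gp, zeq, energy, kind = c("EBF", "EABF")) {
  kind <- match.arg(kind)
  tab <- gp[gp$kind == kind, ]
  if (nrow(tab) == 0L) stop("no rows of kind ", kind, " in G-P table")
  es <- sort(unique(tab$energy_MeV))
  if (energy < min(es) || energy > max(es)) {
    stop(sprintf("energy %.4g MeV outside the G-P grid [%g, %g]",
                 energy, min(es), max(es)))
  }
  j <- which(abs(es - energy) < 1e-12)
  if (length(j) > 0L) {
    out <- .gp_interp_z(tab[abs(tab$energy_MeV - es[j[1]]) < 1e-12, ], zeq)
  } else {
    j <- findInterval(energy, es)
    E1 <- es[j]; E2 <- es[j + 1]
    p1 <- .gp_interp_z(tab[abs(tab$energy_MeV - E1) < 1e-12, ], zeq)
    p2 <- .gp_interp_z(tab[abs(tab$energy_MeV - E2) < 1e-12, ], zeq)
    w2 <- (log(energy) - log(E1)) / (log(E2) - log(E1))
    out <- purrr::map2(p1, p2, function(a, b) (1 - w2) * a + w2 * b)
  }
  tibble::as_tibble(out)
}

.check_params <- function(params) {
  params <- as.list(params)
  need <- c("b", "c", "a", "Xk", "d")
  if (!all(need %in% names(params))) {
    stop("G-P parameters must include: ", paste(need, collapse = ", "))
  }
  params
}

#' G-P dose-multiplication factor K
#'
#' `K(E,x) = c x^a + d [tanh(x/Xk - 2) - tanh(-2)] / [1 - tanh(-2)]`,
#' valid for penetration depths 0 < x <= 40 mfp.
#'
#' @param params List or one-row data frame with `b`, `c`, `a`, `Xk`, `d`.
#' @param x Penetration depths, mfp (vectorized).
#' @return K values.
#' @export
gp_K <- function(params, x) {
  p <- .check_params(params)
  if (any(x <= 0) || any(x > 40)) {
    stop("penetration depth must satisfy 0 < x <= 40 mfp (G-P validity domain)")
  }
  p$c * x^p$a + p$d * (tanh(x / p$Xk - 2) - tanh(-2)) / (1 - tanh(-2))
}

#' G-P buildup factor
#'
#' `B = 1 + (b-1)(K^x - 1)/(K - 1)` for K != 1 and `B = 1 + (b-1) x` in the
#' K -> 1 limit (used whenever |K - 1| < 1e-8, where the generic branch is
#' numerically singular). `B(0) = 1` is the physical boundary condition and
#' is returned for x = 0.
#'
#' @inheritParams gp_K
#' @return Buildup factors (dimensionless, >= 1 for b >= 1).
#' @export
buildup_factor <- function(params, x) {
  p <- .check_params(params)
  if (any(x < 0) || any(x > 40)) {
    stop("penetration depth must satisfy 0 <= x <= 40 mfp (G-P validity domain)")
  }
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- 1
  if (any(!zero)) {
    xs <- x[!zero]
    K <- gp_K(p, xs)
    lim <- abs(K - 1) < 1e-8
    B <- numeric(length(xs))
    B[lim] <- 1 + (p$b - 1) * xs[lim]
    B[!lim] <- 1 + (p$b - 1) * (K[!lim]^xs[!lim] - 1) / (K[!lim] - 1)
    out[!zero] <- B
  }
  out
}

#' Logarithmically spaced photon energy grid
#'
#' @param emin,emax Grid limits, MeV (defaults 0.015 and 15, the standard
#'   G-P tabulation range).
#' @param n Number of grid points (default 25, the standard G-P grid size).
#' @return Increasing numeric vector of energies, MeV.
#' @export
energy_grid <- function(emin = 0.015, emax = 15, n = 25) {
  stopifnot(emin > 0, emax > emin, n >= 2)
  exp(seq(log(emin), log(emax), length.out = n))
}

#' Buildup curves for a compound table
#'
#' Full pipeline per compound and energy: Compton-to-total ratio, Zeq,
#' interpolated G-P parameters, and the buildup factor at each requested
#' penetration depth.
#'
#' @param compounds Data frame with columns `id`, `formula`.
#' @param xs Cross-section table (both channels).
#' @param gp G-P parameter table.
#' @param energies Photon energies, MeV; defaults to the G-P table's grid
#'   restricted to the cross-section table's coverage.
#' @param depths Penetration depths, mfp (default 10, 20, 40).
#' @param kind `"EBF"` or `"EABF"`.
#' @param weights Optional atomic weight table.
#' @return A tibble of class `buildup_curve` with columns `id`, `kind`,
#'   `energy_MeV`, `zeq`, `depth_mfp`, `B`.
#' @export
buildup_curve <- function(compounds, xs, gp, energies = NULL,
                          depths = c(10, 20, 40), kind = c("EBF", "EABF"),
                          weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(compounds), all(c("id", "formula") %in% names(compounds)))
  if (is.null(energies)) {
    es <- sort(unique(gp$energy_MeV[gp$kind == kind]))
    lo <- max(vapply(split(xs$energy_MeV, xs$element), min, numeric(1)))
    hi <- min(vapply(split(xs$energy_MeV, xs$element), max, numeric(1)))
    energies <- es[es >= lo & es <= hi]
  }
  if (any(depths < 0) || any(depths > 40)) {
    stop("penetration depths must lie in [0, 40] mfp (G-P validity domain)")
  }
  out <- purrr::map_dfr(seq_len(nrow(compounds)), function(i) {
    id <- compounds$id[i]; f <- compounds$formula[i]
    purrr::map_dfr(energies, function(e) {
      R <- compton_total_ratio(xs, f, e, weights)
      zres <- equivalent_atomic_number(R, elemental_ratios(xs, e))
      pars <- interpolate_gp_parameters(gp, zres$zeq, e, kind)
      tibble::tibble(
        id = id, kind = kind, energy_MeV = e, zeq = zres$zeq,
        depth_mfp = depths, B = buildup_factor(pars, depths)
      )
    })
  })
  class(out) <- c("buildup_curve", class(out))
  out
}
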