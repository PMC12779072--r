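# Molecular formula handling: parsing, molecular weight, elemental weight
# fractions. Weight fractions are the W_i entering the mixture rule for the
# mass attenuation coefficient of a compound.

# IUPAC standard atomic weights (conventional single values), g/mol.
# Fixed table rather than a runtime lookup so results are identical across
# environments.
.atomic_weights <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.95, K = 39.0983,
  Ca = 40.078, Ti = 47.867, Cr = 51.9961, Mn = 54.938043, Fe = 55.845,
  Ni = 58.6934, Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.90447
)

#' Standard atomic weights
#'
#' The fixed table of IUPAC standard atomic weights used throughout the
#' package. Shipping a fixed table (rather than querying an external source)
#' keeps molecular weights and weight fractions deterministic.
#'
#' @return A tibble with columns `element` and `atomic_weight` (g/mol).
#' @export
#' @examples
#' atomic_weights()
atomic_weights <- function() {
  tibble::tibble(
    element = names(.atomic_weights),
    atomic_weight = unname(.atomic_weights)
  )
}

.weights_vector <- function(weights = NULL) {
  if (is.null(weights)) return(.atomic_weights)
  if (is.data.frame(weights)) {
    stopifnot(all(c("element", "atomic_weight") %in% names(weights)))
    w <- weights$atomic_weight
    names(w) <- weights$element
    weights <- w
  }
  if (any(weights <= 0)) stop("atomic weights must be strictly positive")
  weights
}

#' Parse a molecular formula
#'
#' Parses a flat element-count string such as `"C30H44N6O2"` into integer
#' element counts. The grammar is a repeated (ElementSymbol, optional count)
#' sequence; an omitted count means 1. Parentheses, hydrates, charges and
#' isotopes are not supported.
#'
#' @param formula A single formula string.
#' @param weights Optional atomic weight table (as [atomic_weights()]) used
#'   only to decide which element symbols are recognized.
#' @return A named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C30H44N6O2")
#' parse_formula("CH4")
parse_formula <- function(formula, weights = NULL) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("`formula` must be a single string")
  }
  if (!nzchar(formula)) stop("empty formula")
  w <- .weights_vector(weights)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (length(tokens) == 0L || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  els <- sub("[0-9]*$", "", tokens)
  cnt_str <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt_str), suppressWarnings(as.integer(cnt_str)), 1L)
  unknown <- setdiff(els, names(w))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(cnt <= 0L)) stop("element counts must be positive integers")
  counts <- tapply(cnt, factor(els, levels = unique(els)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Canonical Hill-order formula string
#'
#' Writes element counts back to a formula string in Hill order: carbon
#' first, then hydrogen, then all other elements alphabetically (plain
#' alphabetical order when no carbon is present).
#'
#' @param counts Named integer vector of element counts, as returned by
#'   [parse_formula()].
#' @return A single formula string.
#' @export
#' @examples
#' formula_to_hill(parse_formula("H44O2N6C30"))
formula_to_hill <- function(counts) {
  stopifnot(length(counts) > 0, !is.null(names(counts)))
  els <- names(counts)
  if ("C" %in% els) {
    ord <- c(
      intersect(c("C", "H"), els),
      sort(setdiff(els, c("C", "H")))
    )
  } else {
    ord <- sort(els)
  }
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Molecular weight from element counts
#'
#' @inheritParams formula_to_hill
#' @param weights Optional atomic weight table; defaults to the packaged
#'   IUPAC values.
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' molecular_weight(parse_formula("C30H44N6O2"))
molecular_weight <- function(counts, weights = NULL) {
  w <- .weights_vector(weights)
  missing <- setdiff(names(counts), names(w))
  if (length(missing) > 0L) {
    stop("no atomic weight for element(s): ", paste(missing, collapse = ", "))
  }
  sum(counts * w[names(counts)])
}

#' Elemental weight fractions
#'
#' The mass fraction of each element in a compound: `count * atomic_weight /
#' molecular_weight`. These are the weights W_i of the mixture rule for the
#' compound mass attenuation coefficient.
#'
#' @inheritParams molecular_weight
#' @return Named numeric vector of fractions summing to 1.
#' @export
#' @examples
#' weight_fractions(parse_formula("C30H44N6O2"))
weight_fractions <- function(counts, weights = NULL) {
  w <- .weights_vector(weights)
  mw <- molecular_weight(counts, weights)
  frac <- counts * w[names(counts)] / mw
  frac
}

#' Elemental composition of a compound table
#'
#' Data-frame-first wrapper: takes a compound table (columns `id` and
#' `formula`, e.g. from [read_compounds()]) and returns one row per compound
#' and element with counts, weight fractions and the molecular weight.
#'
#' @param compounds A data frame with columns `id` and `formula`.
#' @param weights Optional atomic weight table.
#' @return A tibble with columns `id`, `element`, `count`, `atomic_weight`,
#'   `weight_fraction`, `molecular_weight`.
#' @export
#' @examples
#' composition(tibble::tibble(id = "2a", formula = "C30H44N6O2"))
composition <- function(compounds, weights = NULL) {
  stopifnot(is.data.frame(compounds), all(c("id", "formula") %in% names(compounds)))
  w <- .weights_vector(weights)
  purrr::map2_dfr(compounds$id, compounds$formula, function(id, f) {
    counts <- parse_formula(f, weights)
    frac <- weight_fractions(counts, weights)
    tibble::tibble(
      id = id,
      element = names(counts),
      count = as.integer(counts),
      atomic_weight = unname(w[names(counts)]),
      weight_fraction = unname(frac),
      molecular_weight = molecular_weight(counts, weights)
    )
  })
}

#' Read a compound definition file
#'
#' Reads a CSV with header `id,formula,density_g_cm3`; the density column
#' may be empty (some workflows only need the density-free mass attenuation
#' coefficient, or infer density from an anchor measurement with
#' [infer_density()]).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `id`, `formula`, `density_g_cm3`; every
#'   formula is validated by parsing.
#' @export
read_compounds <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    formula = readr::col_character(),
    density_g_cm3 = readr::col_double()
  ), comment = "#")
  purrr::walk(x$formula, parse_formula)
  bad <- !is.na(x$density_g_cm3) & x$density_g_cm3 <= 0
  if (any(bad)) {
    stop("non-positive density for compound(s): ", paste(x$id[bad], collapse = ", "))
  }
  x
}
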