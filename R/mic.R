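# Minimal inhibitory concentration (MIC) analysis on two-fold dilution
# ladders: ladder validation, per-organism/per-compound summaries, and the
# compound comparison statistics (one-way ANOVA with Tukey HSD post-hoc).
#
# Broth-microdilution MICs live on a geometric (two-fold) concentration
# ladder, so by default the comparison is run on log2-transformed values;
# the raw scale is available via the `scale` argument.

#' Construct and validate a two-fold dilution ladder
#'
#' A strictly increasing concentration series in which each step is
#' approximately a doubling (ratio within [1.9, 2.1], which absorbs
#' reporting roundings such as 312 -> 625).
#'
#' @param concentrations Increasing numeric vector of concentrations,
#'   ug/mL.
#' @return The validated numeric vector, classed `dilution_ladder`.
#' @export
#' @examples
#' dilution_ladder(c(78, 156, 312, 625, 1250))
dilution_ladder <- function(concentrations) {
  x <- as.numeric(concentrations)
  if (length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop("ladder concentrations must be positive and finite")
  }
  if (any(diff(x) <= 0)) stop("ladder must be strictly increasing")
  if (length(x) > 1L) {
    r <- x[-1] / x[-length(x)]
    if (any(r < 1.9 | r > 2.1)) {
      stop("consecutive ladder ratios must lie in [1.9, 2.1] (two-fold series)")
    }
  }
  structure(x, class = c("dilution_ladder", "numeric"))
}

#' Read a MIC matrix file
#'
#' Wide CSV with header `organism,class,<compound ids...>`, `NT` (or empty)
#' marking untested cells. Returned in long (tidy) form.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `organism`, `class`, `compound`, `mic`
#'   (ug/mL, `NA` = not tested).
#' @export
read_mic_matrix <- function(path) {
  x <- readr::read_csv(path, comment = "#", na = c("NT", "N.T", "NA", ""),
                       col_types = readr::cols(
                         organism = readr::col_character(),
                         class = readr::col_character(),
                         .default = readr::col_double()
                       ))
  if (!all(c("organism", "class") %in% names(x))) {
    stop("MIC file must have `organism` and `class` columns")
  }
  long <- tidyr::pivot_longer(x, cols = -c("organism", "class"),
                              names_to = "compound", values_to = "mic")
  bad <- !is.na(long$mic) & long$mic <= 0
  if (any(bad)) stop("MIC values must be positive")
  long
}

#' Validate MIC values against a dilution ladder
#'
#' Reports (does not throw) every tested cell whose value is not a ladder
#' member.
#'
#' @param mic Long MIC tibble (see [read_mic_matrix()]).
#' @param ladder A [dilution_ladder()].
#' @return A tibble of violations (`organism`, `compound`, `mic`); zero
#'   rows when every tested value sits on the ladder.
#' @export
validate_mic_series <- function(mic, ladder) {
  stopifnot(is.data.frame(mic), all(c("organism", "compound", "mic") %in% names(mic)))
  if (length(ladder) == 0L) stop("ladder must be non-empty")
  tested <- mic[!is.na(mic$mic), ]
  if (nrow(tested) == 0L) {
    return(tibble::tibble(organism = character(), compound = character(),
                          mic = numeric()))
  }
  on_ladder <- vapply(tested$mic, function(v) {
    any(abs(v - ladder) / ladder < 1e-8)
  }, logical(1))
  tibble::as_tibble(tested[!on_ladder, c("organism", "compound", "mic")])
}

#' Summarize a MIC matrix
#'
#' Two views of the activity landscape: per organism, the compound(s)
#' attaining the minimum MIC (ties listed, sorted); per compound, how many
#' organisms sit at each MIC level.
#'
#' @param mic Long MIC tibble.
#' @return A list with tibbles `best_by_organism` (`organism`, `best_mic`,
#'   `compounds`) and `activity_profile` (`compound`, `mic`, `n_organisms`).
#' @export
mic_summary <- function(mic) {
  stopifnot(is.data.frame(mic), all(c("organism", "compound", "mic") %in% names(mic)))
  tested <- mic[!is.na(mic$mic), ]
  if (nrow(tested) == 0L) stop("no tested MIC values")
  best <- tested |>
    dplyr::group_by(.data$organism) |>
    dplyr::summarise(
      best_mic = min(.data$mic),
      compounds = paste(sort(.data$compound[.data$mic == min(.data$mic)]),
                        collapse = ","),
      .groups = "drop"
    )
  profile <- tested |>
    dplyr::count(.data$compound, .data$mic, name = "n_organisms") |>
    dplyr::arrange(.data$compound, .data$mic)
  list(best_by_organism = best, activity_profile = profile)
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares decomposition:
#' `F = MSB / MSW` with `df = (k - 1, N - k)` and the p-value from the F
#' distribution. When the group means are all equal (zero between-group sum
#' of squares) the statistic is 0 and p = 1.
#'
#' @param data A data frame.
#' @param response Column with the numeric response (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @return An object of class `oneway_anova`: F statistic, degrees of
#'   freedom, p-value, group means and the sums of squares. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
#' one_way_anova(d, y, g)
one_way_anova <- function(data, response, group) {
  stopifnot(is.data.frame(data))
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  ns <- table(g)
  k <- length(ns); N <- length(y)
  if (k < 2L) stop("need at least two groups")
  if (all(ns < 2L)) stop("need at least one group with two or more observations")
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssb <= .Machine$double.eps * max(1, sum(y^2))) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(
    F = f, df_between = df1, df_within = df2, p = p,
    ss_between = ssb, ss_within = ssw,
    means = tibble::tibble(group = names(means), n = as.integer(ns),
                           mean = as.numeric(means)),
    n = N
  ), class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparison after a one-way layout using the studentized range
#' distribution; the Tukey-Kramer standard error
#' `sqrt(MSW/2 (1/n_i + 1/n_j))` handles unbalanced groups. Adjusted
#' p-values come from the studentized range distribution with `k` groups
#' and the within-group degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble of class `tukey_hsd` with columns `group1`, `group2`,
#'   `mean_diff` (group2 - group1), `se`, `q`, `adj_p`, `significant`;
#'   attributes `alpha`, `k`, `df`.
#' @export
#' @examples
#' d <- data.frame(y = c(rnorm(5), rnorm(5, 3)), g = rep(c("a", "b"), each = 5))
#' tukey_hsd(d, y, g)
tukey_hsd <- function(data, response, group, alpha = 0.05) {
  stopifnot(is.data.frame(data), alpha > 0, alpha < 1)
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  ns <- table(g); k <- length(ns); N <- length(y)
  if (k < 2L) stop("need at least two groups")
  df <- N - k
  if (df < 1L) stop("no residual degrees of freedom")
  means <- tapply(y, g, mean)
  msw <- sum((y - means[g])^2) / df
  grp <- sort(names(ns))
  pairs <- utils::combn(grp, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- means[[g2]] - means[[g1]]
    se <- sqrt(msw / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
    } else {
      q <- abs(diff) / se
    }
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, mean_diff = diff, se = se,
                   q = q, adj_p = p, significant = p < alpha)
  })
  attr(out, "alpha") <- alpha
  attr(out, "k") <- k
  attr(out, "df") <- df
  class(out) <- c("tukey_hsd", class(out))
  out
}

#' MIC compound comparison pipeline
#'
#' The compound comparison applied to a MIC matrix: one observation per
#' tested (compound, organism) cell, organisms acting as replicates,
#' compounds as groups. By default MICs are compared on the log2 scale
#' (dilution data are geometric); `scale = "raw"` uses the raw ug/mL
#' values. Untested cells are excluded, never imputed.
#'
#' @param mic Long MIC tibble (see [read_mic_matrix()]).
#' @param scale `"log2"` (default) or `"raw"`.
#' @param alpha Significance level for the Tukey comparisons.
#' @return A list with elements `anova` (class `oneway_anova`) and `tukey`
#'   (class `tukey_hsd`).
#' @export
mic_compare <- function(mic, scale = c("log2", "raw"), alpha = 0.05) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(mic), all(c("compound", "mic") %in% names(mic)))
  tested <- mic[!is.na(mic$mic), ]
  if (nrow(tested) == 0L) stop("no tested MIC values")
  tested$value <- if (scale == "log2") log2(tested$mic) else tested$mic
  list(
    anova = one_way_anova(tested, value, compound),
    tukey = tukey_hsd(tested, value, compound, alpha = alpha)
  )
}
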