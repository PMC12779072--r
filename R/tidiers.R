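# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-way ANOVA fit
#'
#' @param x An `oneway_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per stratum (between, within): `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`.
#' @export
tidy.oneway_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$ss_within / x$df_within),
    statistic = c(x$F, NA_real_),
    p.value = c(x$p, NA_real_)
  )
}

#' Glance at a one-way ANOVA fit
#'
#' @param x An `oneway_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p.value`, `df_between`,
#'   `df_within`, `n_groups`, `n_obs`.
#' @export
glance.oneway_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, p.value = x$p,
    df_between = x$df_between, df_within = x$df_within,
    n_groups = nrow(x$means), n_obs = x$n
  )
}
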