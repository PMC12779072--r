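# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an attenuation profile
#'
#' Log-log curves of the chosen attenuation parameter against photon
#' energy, one line per compound.
#'
#' @param object An [attenuation_profile()] tibble.
#' @param parameter One of `"mac"`, `"lac"`, `"hvl"`, `"mfp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attenuation_profile <- function(object,
                                         parameter = c("mac", "lac", "hvl", "mfp"),
                                         ...) {
  parameter <- match.arg(parameter)
  col <- c(mac = "mac_cm2_g", lac = "lac_cm1", hvl = "hvl_cm",
           mfp = "mfp_cm")[[parameter]]
  lab <- c(mac = "MAC (cm²/g)", lac = "LAC (cm⁻¹)",
           hvl = "HVL (cm)", mfp = "MFP (cm)")[[parameter]]
  if (all(is.na(object[[col]]))) {
    stop("no values for parameter '", parameter,
         "' (density missing for all compounds?)")
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$energy_MeV, y = .data[[col]], colour = .data$id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Photon energy (MeV)", y = lab, colour = "Compound") +
    ggplot2::theme_minimal()
}

#' Plot buildup curves
#'
#' Buildup factor against photon energy on log-log axes, coloured by
#' penetration depth and faceted by compound.
#'
#' @param object A [buildup_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.buildup_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$energy_MeV, y = .data$B,
    colour = factor(.data$depth_mfp), group = .data$depth_mfp
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$id)) +
    ggplot2::labs(x = "Photon energy (MeV)",
                  y = sprintf("%s buildup factor", object$kind[1]),
                  colour = "Depth (mfp)") +
    ggplot2::theme_minimal()
}

#' MIC heat map
#'
#' Organism-by-compound tile plot of MIC values on the log2 colour scale;
#' untested cells are blank.
#'
#' @param mic Long MIC tibble (see [read_mic_matrix()]).
#' @return A ggplot object.
#' @export
plot_mic_heatmap <- function(mic) {
  stopifnot(is.data.frame(mic), all(c("organism", "compound", "mic") %in% names(mic)))
  ggplot2::ggplot(mic, ggplot2::aes(
    x = .data$compound, y = .data$organism, fill = log2(.data$mic)
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$mic), "NT", .data$mic)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1, na.value = "grey90") +
    ggplot2::labs(x = "Compound", y = NULL, fill = "log2 MIC\n(µg/mL)") +
    ggplot2::theme_minimal()
}

#' Plot Tukey HSD comparisons
#'
#' Mean differences with simultaneous confidence intervals at the fit's
#' family-wise level, coloured by significance.
#'
#' @param object A [tukey_hsd()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tukey_hsd <- function(object, ...) {
  alpha <- attr(object, "alpha")
  qc <- stats::qtukey(1 - alpha, attr(object, "k"), attr(object, "df"))
  d <- tibble::as_tibble(object)
  d$pair <- paste(d$group2, "-", d$group1)
  d$lo <- d$mean_diff - qc * d$se
  d$hi <- d$mean_diff + qc * d$se
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$mean_diff, y = .data$pair, colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Mean difference", y = NULL,
                  colour = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
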