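#' Plot calibrated flux time courses
#'
#' @param flux A `FluxTimeCourse` tibble from [calibrate_traces()].
#' @return A ggplot: cumulative acid production and oxygen consumption over
#'   time, one panel each, coloured by well.
#' @export
plot_flux <- function(flux) {
  check_columns(flux, c("well", "time_h", "cumulative_acid",
                        "cumulative_o2"), "flux")
  long <- tidyr::pivot_longer(flux, c("cumulative_acid", "cumulative_o2"),
                              names_to = "series", values_to = "mol")
  long$series <- dplyr::recode(long$series,
                               cumulative_acid = "H+ production",
                               cumulative_o2 = "O2 consumption")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$mol,
                                     colour = .data$well)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "cumulative flux (mol)") +
    ggplot2::theme_minimal()
}

#' Plot a lysosome-to-nucleus distance histogram
#'
#' @param distance Result of [nucleus_distance_histogram()].
#' @return A ggplot with the half-maximal-abundance marker.
#' @export
plot_distance_histogram <- function(distance) {
  h <- distance$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = if (nrow(h) > 1) diff(h$bin_mid[1:2]) else 2,
                      fill = "grey70") +
    ggplot2::labs(x = "distance to nearest nucleus (px)", y = "lysosomes") +
    ggplot2::theme_minimal()
  if (is.finite(distance$half_max_distance)) {
    p <- p + ggplot2::geom_vline(xintercept = distance$half_max_distance,
                                 colour = "darkgreen", linetype = 2)
  }
  p
}

#' Scatter of hypoxic response under alkalosis versus acidosis
#'
#' @param clusters Result of [cluster_hypoxic_responses()].
#' @return A ggplot of per-protein log2 fold-changes coloured by cluster,
#'   with the line of identity.
#' @export
plot_response_scatter <- function(clusters) {
  ggplot2::ggplot(clusters$assignments,
                  ggplot2::aes(x = .data$lfc_hyp_alk, y = .data$lfc_hyp_acid,
                               colour = .data$cluster)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "hypoxic response, alkaline pH (log2 FC)",
                  y = "hypoxic response, acidic pH (log2 FC)") +
    ggplot2::theme_minimal()
}
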