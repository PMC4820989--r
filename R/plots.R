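#' Plot the targeting-domain length distribution
#'
#' Bar plot of domain lengths normalised to the 20-base bin within each
#' replicate.
#'
#' @param histogram Output of [length_histogram()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$domain_length, y = .data$normalized,
                               group = .data$replicate)) +
    ggplot2::geom_col(position = "dodge", fill = "steelblue",
                      colour = "grey20") +
    ggplot2::labs(x = "targeting-domain length (bases)",
                  y = "count / length-20 count") +
    ggplot2::theme_minimal()
}

#' Plot observed vs theoretical neighbour-distance distributions
#'
#' Empirical cumulative distributions of the NGG neighbour distances for the
#' observed library and for the full theoretical site set.
#'
#' @param observed,theoretical `distance_stats` objects.
#' @return A ggplot object.
#' @export
plot_neighbor_distances <- function(observed, theoretical) {
  df <- bind_rows(
    mutate(observed$distances, set = "observed"),
    mutate(theoretical$distances, set = "theoretical"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_colour_manual(values = c(observed = "firebrick",
                                            theoretical = "steelblue")) +
    ggplot2::labs(x = "neighbour distance (bp)", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-position enrichment track
#'
#' Lollipop-style track of the best positive log2 enrichment per position,
#' coloured by strand, facetted by replicate and bin.
#'
#' @param track Output of [positional_track()].
#' @return A ggplot object.
#' @export
plot_enrichment_track <- function(track) {
  ggplot2::ggplot(track,
                  ggplot2::aes(x = .data$last_base_pos + 1, y = .data$score,
                               colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$last_base_pos + 1,
                                       yend = 0)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`+` = "blue", `-` = "red")) +
    ggplot2::facet_grid(replicate ~ bin) +
    ggplot2::labs(x = "position (bp)", y = "log2 enrichment",
                  colour = "strand") +
    ggplot2::theme_minimal()
}

#' Autoplot a window-cluster scan profile
#'
#' @param object A `scan_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos + 1, y = .data$value)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "window centre position (bp)",
                  y = "-log10(window probability)") +
    ggplot2::theme_minimal()
  if (all(c("replicate", "bin") %in% names(object))) {
    p <- p + ggplot2::facet_grid(replicate ~ bin)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a saturation curve
#'
#' @param curve Output of [saturation_curve()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$size, y = .data$n_unique,
                               group = .data$draw)) +
    ggplot2::geom_line(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "subsampled mapped reads", y = "unique sgRNAs") +
    ggplot2::theme_minimal()
}
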