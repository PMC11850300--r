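#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_col geom_line geom_point scale_x_log10 scale_y_log10 labs
#'   theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot a triad permutation null distribution
#'
#' Histogram of simulated triad counts with the observed count marked by
#' a vertical line -- the standard view of a permutation test.
#'
#' @param object A `triad_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.triad_sim <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$sim_count)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "firebrick",
               linewidth = 0.8) +
    labs(x = "simulated triad count", y = "replicates",
         title = paste0(object$protein, ": observed ", object$observed,
                        ", empirical p = ", signif(object$empirical_p, 3))) +
    theme_minimal()
}

#' Plot a chromatin-state distribution
#'
#' Normalized density (observed fraction over genomic fraction) per state
#' group; 1 means no enrichment.
#'
#' @param object A `state_distribution` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.state_distribution <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$label, .data$normalized_density),
                     y = .data$normalized_density)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "normalized density") +
    theme_minimal()
}

#' Plot a distance-scaling profile
#'
#' Per-bin contact density (weight) against genomic distance from the
#' source gene on log-log axes; a power-law decline appears as a straight
#' line.
#'
#' @param bins A [scaling_weights()] tibble.
#' @return A ggplot.
#' @export
plot_rd_scaling <- function(bins) {
  df <- bins |> filter(.data$n_contacts > 0, .data$lo > 0)
  ggplot(df, aes(x = sqrt(.data$lo * .data$hi), y = .data$weight)) +
    geom_line(colour = "grey50") +
    geom_point() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "distance from gene (bp)", y = "scaling weight") +
    theme_minimal()
}
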