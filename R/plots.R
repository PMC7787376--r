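#' Radar plot of activity sentiment profiles
#'
#' The conventional polar display of the activity-by-dimension mean
#' matrix: one closed line per activity over the three VAD axes.
#'
#' @param radar A tibble from [radar_data()].
#' @param limits Radial limits (default `c(1, 9)`, the rating scale).
#' @return A ggplot object.
#' @export
plot_radar <- function(radar, limits = c(1, 9)) {
  df <- radar |>
    dplyr::mutate(
      dimension = factor(.data$dimension, levels = vad_dimensions),
      activity = factor(.data$activity, levels = vad_activities)
    )
  closing <- df |> dplyr::filter(.data$dimension == vad_dimensions[1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dimension, y = .data$mean,
                                   group = .data$activity,
                                   colour = .data$activity,
                                   linetype = .data$activity)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_polar() +
    ggplot2::scale_y_continuous(limits = limits) +
    ggplot2::labs(x = NULL, y = "mean sentiment score (1-9)",
                  colour = "activity", linetype = "activity") +
    ggplot2::theme_minimal()
}

#' Plot a normalised score histogram
#'
#' Overlaid per-series normalised distributions (each series sums to 1),
#' the standard way to compare a response word-set's score distribution
#' against the full lexicon.
#'
#' @param object A `vad_histogram` from [score_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vad_histogram <- function(object, ...) {
  dim <- attr(object, "dimension")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$prop,
                                       fill = .data$series)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55,
                      width = object$bin_hi[1] - object$bin_lo[1]) +
    ggplot2::labs(x = paste(dim, "score"), y = "proportion of words",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
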