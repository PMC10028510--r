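#' Plot a study result
#'
#' Two stacked panels in the layout used throughout the package: the
#' inputs (per-game score and, when present, session-mean heart rate with
#' the ceiling drawn as a dashed line) on top, the end-of-session
#' difficulty trace below.
#'
#' @param object A `study_result` or `study_set`.
#' @param hr_max Ceiling to draw on the heart-rate panel (bpm); `NULL`
#'   suppresses the line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.study_result <- function(object, hr_max = 180, ...) {
  plot_trace(tidy(object), hr_max = hr_max)
}

#' @rdname autoplot.study_result
#' @exportS3Method ggplot2::autoplot
autoplot.study_set <- function(object, hr_max = 180, ...) {
  plot_trace(tidy(object), hr_max = hr_max)
}

plot_trace <- function(trace, hr_max = 180) {
  long <- trace |>
    tidyr::pivot_longer(cols = c("score", "mean_hr", "end_difficulty"),
                        names_to = "panel", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(panel = factor(
      .data$panel, levels = c("score", "mean_hr", "end_difficulty"),
      labels = c("score", "mean heart rate [bpm]", "difficulty")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$game, y = .data$value,
                                          colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "game", y = NULL, colour = "mode") +
    ggplot2::theme_minimal()
  if (!is.null(hr_max) && any(long$panel == "mean heart rate [bpm]")) {
    p <- p + ggplot2::geom_hline(
      data = data.frame(panel = factor("mean heart rate [bpm]",
                                       levels = levels(long$panel)),
                        y = hr_max),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed")
  }
  p
}
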