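# ggplot2 displays for the main result types.

#' Plot a stretch of a five-channel stream
#'
#' @param object A `pfec_stream`.
#' @param from,to Sample range to display (0-based; default first 2000).
#' @param ... Unused.
#' @return A ggplot object; truth intervals, when present, are shaded.
#' @method autoplot pfec_stream
#' @export
autoplot.pfec_stream <- function(object, from = 0, to = 2000, ...) {
  dat <- as_tibble(object) |>
    dplyr::filter(.data$t >= from, .data$t < to) |>
    tidyr::pivot_longer(c("I1", "I2", "I3", "I4", "F"),
                        names_to = "channel", values_to = "intensity")
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "sample", y = "intensity (detector units)")
  truth <- stream_truth(object)
  truth <- truth[truth$start < to & truth$end > from, ]
  if (nrow(truth) > 0) {
    p <- p + ggplot2::geom_rect(
      data = truth, inherit.aes = FALSE, alpha = 0.15, fill = "red",
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Heat-map display of a confusion matrix
#'
#' @param object A `pfec_confusion`.
#' @param ... Unused.
#' @return A ggplot object (rows actual, columns predicted, cell counts).
#' @method autoplot pfec_confusion
#' @export
autoplot.pfec_confusion <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$predicted, .data$actual,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("overall accuracy %.2f%%", 100 * object$accuracy),
      x = "predicted", y = "actual")
}

#' Stacked-bar display of sample compositions
#'
#' @param object A `pfec_composition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pfec_composition
#' @export
autoplot.pfec_composition <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$sample_id, .data$proportion,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "proportion", fill = "category")
}
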