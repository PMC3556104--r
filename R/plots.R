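# Diagnostic plots for the array and regulon stages.

#' MA plot of a lowess-corrected hybridization
#'
#' @param array Output of [lowess_normalize()] (columns `a`, `m`).
#' @return A ggplot.
#' @export
plot_ma <- function(array) {
  stopifnot(all(c("a", "m") %in% names(array)))
  ggplot2::ggplot(array, ggplot2::aes(.data$a, .data$m)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "A = 0.5 log2(cy3 * cy5)",
                  y = "corrected M = log2(cy3/cy5)")
}

#' Time-course profiles colored by temporal class
#'
#' @param profiles Long profile tibble from [timecourse_ratios()].
#' @param classes Tibble from [classify_temporal_response()].
#' @param thresholds Optional tibble of induction thresholds
#'   (`time_point`, `value`) drawn as crossbars.
#' @return A ggplot.
#' @export
plot_temporal_classes <- function(profiles, classes, thresholds = NULL) {
  dat <- profiles |>
    left_join(classes |> select("orf_id", "class"), by = "orf_id")
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_point, .data$value,
                                         group = .data$orf_id,
                                         colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(
      fast = "firebrick", slow = "steelblue", none = "grey70"
    )) +
    ggplot2::labs(x = "minutes post-starvation", y = "log2 fold change vs t=0")
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_point(
      data = thresholds, inherit.aes = FALSE,
      ggplot2::aes(.data$time_point, .data$value), shape = 3, size = 3
    )
  }
  p
}

#' FACS gate view: scatter gate and YFP threshold
#'
#' @param events FACS event tibble (see [simulate_facs_events()]).
#' @param scatter_low,scatter_high Gate bounds.
#' @return A ggplot of forward vs side scatter with the gate rectangle.
#' @export
plot_facs_gate <- function(events, scatter_low = 50000, scatter_high = 150000) {
  ggplot2::ggplot(events, ggplot2::aes(.data$fsc, .data$ssc)) +
    ggplot2::geom_point(alpha = 0.1, size = 0.4) +
    ggplot2::annotate("rect", xmin = scatter_low, xmax = scatter_high,
                      ymin = scatter_low, ymax = scatter_high,
                      fill = NA, colour = "firebrick") +
    ggplot2::labs(x = "forward scatter", y = "side scatter")
}
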