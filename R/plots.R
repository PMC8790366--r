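#' Plot a trace with classified events
#'
#' Raw axes over time with dive and take-off spans shaded, for visual QC of
#' the classifier.
#'
#' @param trace An [accel_trace()].
#' @param events Event tibble from [classify_behaviour()] (optional).
#' @param window Optional numeric length-2 time window (s) to zoom into.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, window = NULL) {
  df <- tibble::as_tibble(trace)
  if (!is.null(window)) {
    df <- df[df$t >= window[1] & df$t <= window[2], ]
    if (!is.null(events)) {
      events <- events[events$end_s >= window[1] & events$start_s <= window[2], ]
    }
  }
  long <- tidyr::pivot_longer(df, c("ax", "ay", "az"),
                              names_to = "axis", values_to = "g")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$g)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   fill = .data$kind),
      ymin = -Inf, ymax = Inf, alpha = 0.2, inherit.aes = FALSE
    ) + ggplot2::scale_fill_manual(values = c(dive = "steelblue",
                                              takeoff = "orange"))
  }
  p
}

#' Posterior diet proportions
#'
#' Boxplots of posterior draws per source, faceted by group.
#'
#' @param object A `diet_mix` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diet_mix
#' @export
autoplot.diet_mix <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(.data$source, .data$p)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "diet proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Minimum success rates by sex
#'
#' Boxplot of per-bird minimum dive-success percentages for each sex.
#'
#' @param trips Trip-summary tibble with `sex` and `pct_success_min`.
#' @return A ggplot object.
#' @export
plot_min_success <- function(trips) {
  known <- trips[trips$sex %in% c("female", "male"), ]
  ggplot2::ggplot(known,
                  ggplot2::aes(.data$sex, .data$pct_success_min)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL,
                  y = "minimum % of dives that must succeed") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
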