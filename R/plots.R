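#' Plot discrimination performance over time
#'
#' Az time course of a sliding discriminant with its peak marked; pass a
#' bootstrap threshold to draw the significance line.
#'
#' @param object An `fda_model` from [sliding_loo_az()].
#' @param threshold Optional Az significance threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fda_model
#' @export
autoplot.fda_model <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object$az, ggplot2::aes(.data$time * 1000, .data$az)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_time * 1000,
                        linetype = "dotted") +
    ggplot2::labs(x = "Time from stimulus (ms)", y = "Az (LOO)",
                  title = sprintf("Peak Az %.2f, shrinkage %g",
                                  object$peak_az, object$gamma))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot condition-mean component traces
#'
#' @param object A [component_timecourses()] result.
#' @param by Label column defining the conditions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot component_timecourse
#' @export
autoplot.component_timecourse <- function(object, by = "difficulty_label",
                                          ...) {
  cm <- condition_means(object, by = by)
  ggplot2::ggplot(cm, ggplot2::aes(.data$time * 1000, .data$mean_y,
                                   color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from stimulus (ms)", y = "Component (z)",
                  color = by)
}

#' Psychometric and chronometric summaries of a trial table
#'
#' Fraction of play choices (and mean RT) per reward-probability level and
#' context.
#'
#' @param trials Behavioral trial table with `context`, `p_level`, `choice`,
#'   `rt_s`.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(trials) {
  d <- as_tibble(trials) |>
    dplyr::group_by(.data$context, .data$p_level) |>
    dplyr::summarise(p_play = mean(.data$choice == 1), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$p_level, .data$p_play,
                                  color = .data$context)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Reward-probability level", y = "P(play)")
}

#' @rdname plot_psychometric
#' @export
plot_chronometric <- function(trials) {
  d <- as_tibble(trials) |>
    dplyr::group_by(.data$context, .data$p_level) |>
    dplyr::summarise(mean_rt = mean(.data$rt_s), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$p_level, .data$mean_rt,
                                  color = .data$context)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Reward-probability level", y = "Mean RT (s)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
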