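#' @method autoplot recall_trajectory
#' @export
autoplot.recall_trajectory <- function(object, r_thresh = NULL, ...) {
  df <- tidy(object)
  if (is.null(r_thresh)) r_thresh <- object$config$r_thresh
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rate,
                                   colour = factor(.data$memory))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = r_thresh, linetype = "dashed") +
    ggplot2::labs(x = "time", y = "memory mean rate", colour = "memory") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative recall curve
#'
#' @param curve Output of [accumulation_curve()].
#' @return A ggplot object.
#' @export
plot_accumulation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time,
                                      y = .data$mean_recalled)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_recalled - .data$se,
                                      ymax = .data$mean_recalled + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "mean distinct items recalled") +
    ggplot2::theme_minimal()
}

#' Plot a transition-rank distribution
#'
#' @param dist Output of [transition_rank_distribution()].
#' @return A ggplot object.
#' @export
plot_rank_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$rank,
                                     y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "similarity rank of transition (high = most similar)",
                  y = "probability") +
    ggplot2::theme_minimal()
}

#' @method autoplot performance_sweep
#' @export
autoplot.performance_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$mean_recalled)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_recalled - .data$se,
                   ymax = .data$mean_recalled + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = unique(object$parameter),
                  y = "mean distinct items recalled") +
    ggplot2::theme_minimal()
}

#' Plot conditional IRT curves
#'
#' One line per total number of items recalled, mean IRT against transition
#' index.
#'
#' @param irt_stats Output of [irt_statistics()].
#' @return A ggplot object.
#' @export
plot_conditional_irt <- function(irt_stats) {
  ggplot2::ggplot(irt_stats$conditional,
                  ggplot2::aes(x = .data$transition, y = .data$mean_irt,
                               colour = factor(.data$total_recalled))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transition index", y = "mean IRT",
                  colour = "items recalled") +
    ggplot2::theme_minimal()
}
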