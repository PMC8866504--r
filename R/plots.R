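#' Plot a locomotion track
#'
#' @param object A `worm_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot worm_trajectory
#' @export
autoplot.worm_trajectory <- function(object, ...) {
  env <- attr(object, "env")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
  if (!is.null(env) && env$kind != "isotropic") {
    p <- p + ggplot2::annotate("point", x = env$peak[1], y = env$peak[2],
                               colour = "red", shape = 8, size = 3)
  }
  p
}

#' Plot binned turning-bias relationship curves
#'
#' One panel per predictor (bearing, normal gradient, translational
#' gradient); points are bin means with SD error bars, gray points the
#' sign-split means.
#'
#' @param curves Output of [relationship_curves()].
#' @return A ggplot.
#' @export
plot_relationship_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$bin_mid, .data$mean_bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_pos),
                        colour = "grey60", size = 1, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_neg),
                        colour = "grey60", size = 1, na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_bias - .data$sd_bias,
                                        ymax = .data$mean_bias + .data$sd_bias),
                           width = 0, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "turning bias (deg)")
}

#' Plot the GA fitness trajectory
#'
#' @param object A `klinotaxis_ga`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot klinotaxis_ga
#' @export
autoplot.klinotaxis_ga <- function(object, ...) {
  lb <- tidy(object)
  lb_long <- tidyr::pivot_longer(lb, c("best", "mean"),
                                 names_to = "stat", values_to = "fitness")
  ggplot2::ggplot(lb_long,
                  ggplot2::aes(.data$generation, .data$fitness,
                               linetype = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (mean CI)", linetype = NULL)
}

#' Plot the turning-rate distribution of random-walk tracks
#'
#' Histogram of pooled per-cycle turning rates with the reference normal
#' density overlaid.
#'
#' @param object A `random_walk_stats`.
#' @param tracks The track list the statistics were computed from (used to
#'   pool the rates); when omitted only the per-track summary is shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot random_walk_stats
#' @export
autoplot.random_walk_stats <- function(object, tracks = NULL, ...) {
  if (!is.null(tracks)) {
    rates <- unlist(lapply(tracks, function(tr) {
      if (inherits(tr, "worm_trajectory")) cycle_series(tr)$turning_rate
      else tr$turning_rate
    }))
    rates <- rates[is.finite(rates)]
    df <- tibble(rate = rates)
    ggplot2::ggplot(df, ggplot2::aes(.data$rate)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 30, fill = "grey80", colour = "grey40") +
      ggplot2::stat_function(fun = stats::dnorm,
                             args = list(mean = object$target_mu,
                                         sd = object$target_sigma),
                             linetype = 2, colour = "blue") +
      ggplot2::labs(x = "turning rate (deg/mm)", y = "density")
  } else {
    ggplot2::ggplot(object$per_track, ggplot2::aes(.data$mu, .data$sigma)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "track mean (deg/mm)", y = "track SD (deg/mm)")
  }
}

#' Plot an ablation battery
#'
#' Bar height is the across-model mean CI, error bars the s.e.m.
#'
#' @param battery Output of [ablation_battery()].
#' @return A ggplot.
#' @export
plot_ablation_battery <- function(battery) {
  summ <- attr(battery, "summary")
  ggplot2::ggplot(summ,
                  ggplot2::aes(stats::reorder(.data$ablation, -.data$mean_ci),
                               .data$mean_ci)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ci - .data$sem_ci,
                                        ymax = .data$mean_ci + .data$sem_ci),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean CI") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
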