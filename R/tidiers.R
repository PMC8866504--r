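#' Tidy a genetic-algorithm fit
#'
#' Returns the per-generation logbook: best and mean population fitness and
#' the cumulative number of fitness evaluations.
#'
#' @param x A `klinotaxis_ga`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy klinotaxis_ga
#' @export
tidy.klinotaxis_ga <- function(x, ...) {
  x$logbook
}

#' @rdname tidy.klinotaxis_ga
#' @method glance klinotaxis_ga
#' @export
glance.klinotaxis_ga <- function(x, ...) {
  tibble(
    generations = x$generations,
    best_fitness = x$best_fitness,
    best_reliability = x$best_reliability,
    mean_fitness = mean(x$fitness),
    n_successful = length(successful_models(x)),
    n_evals = x$n_evals,
    pop_size = nrow(x$population)
  )
}

#' Tidy random-walk statistics
#'
#' `tidy()` returns the per-track table (mean, SD, and K-S P value of the
#' turning rate); `glance()` the pooled one-row summary including the lag
#' correlations.
#'
#' @param x A `random_walk_stats`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy random_walk_stats
#' @export
tidy.random_walk_stats <- function(x, ...) {
  x$per_track
}

#' @rdname tidy.random_walk_stats
#' @method glance random_walk_stats
#' @export
glance.random_walk_stats <- function(x, ...) {
  lag6 <- x$lag$correlation[x$lag$lag == 6]
  lag12 <- x$lag$correlation[x$lag$lag == 12]
  tibble(
    n_tracks = nrow(x$per_track),
    mean_mu = mean(x$per_track$mu),
    sd_mu = sd(x$per_track$mu),
    mean_sigma = mean(x$per_track$sigma),
    sd_sigma = sd(x$per_track$sigma),
    mean_ks_p = mean(x$per_track$ks_p),
    lag_corr_6s = if (length(lag6)) lag6 else NA_real_,
    lag_corr_12s = if (length(lag12)) lag12 else NA_real_
  )
}

#' Tidy a liquid-synapse SD fit
#'
#' @param x A `liquid_fit`.
#' @param ... Unused.
#' @return `tidy()`: per-edge SDs; `glance()`: one-row summary with the
#'   achieved turning-rate statistics.
#' @method tidy liquid_fit
#' @export
tidy.liquid_fit <- function(x, ...) {
  con <- x$model$connectome
  tibble(pre = con$chem$pre, post = con$chem$post,
         w_bar = x$model$w_c, sigma = x$sigma)
}

#' @rdname tidy.liquid_fit
#' @method glance liquid_fit
#' @export
glance.liquid_fit <- function(x, ...) {
  st <- if (!is.null(x$stats)) glance(x$stats) else
    tibble(mean_mu = NA_real_, mean_sigma = NA_real_, mean_ks_p = NA_real_)
  tibble(scale = x$scale,
         achieved_mu = st$mean_mu,
         achieved_sigma = st$mean_sigma,
         mean_ks_p = st$mean_ks_p,
         target_mu = x$target_mu,
         target_sigma = x$target_sigma)
}
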