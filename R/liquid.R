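#' Draw liquid-synapse guideposts
#'
#' Each chemical synapse strength is a slow stochastic process: every
#' `delta_t` seconds an independent normal "guidepost" value is drawn around
#' the evolved mean strength, and the strength moves linearly between
#' consecutive guideposts. This samples the guidepost sequences; negative
#' draws are clamped to zero so strengths stay non-negative.
#'
#' @param w_bar Per-edge mean strengths (the evolved fixed weights).
#' @param sigma Per-edge SDs (>= 0); recycled against `w_bar`.
#' @param n_guideposts Number of guideposts per edge.
#' @param seed Integer seed.
#' @param clamp Clamp negative draws at zero (default TRUE).
#' @return Matrix `length(w_bar)` x `n_guideposts`.
#' @export
sample_guideposts <- function(w_bar, sigma, n_guideposts, seed, clamp = TRUE) {
  sigma <- rep_len(sigma, length(w_bar))
  if (any(sigma < 0)) abort("sigma must be non-negative")
  stopifnot(n_guideposts >= 1)
  withr_seed(seed, {
    # row-by-row so each edge's stream is a contiguous block: adding edges
    # later does not reshuffle earlier edges' draws
    g <- matrix(0, length(w_bar), n_guideposts)
    for (e in seq_along(w_bar)) {
      g[e, ] <- rnorm(n_guideposts, w_bar[e], sigma[e])
    }
  })
  if (clamp) g[g < 0] <- 0
  g
}

#' Build a liquid-synapse schedule
#'
#' @param w_bar,sigma As in [sample_guideposts()].
#' @param duration Simulated time (s) the schedule must cover.
#' @param delta_t Guidepost interval (s), 12 by default.
#' @param t0 Schedule start offset (s), >= 0.
#' @param seed Integer seed.
#' @return A `liquid_schedule` object.
#' @export
liquid_schedule <- function(w_bar, sigma, duration, delta_t = 12, t0 = 0,
                            seed = 1) {
  stopifnot(delta_t > 0, t0 >= 0, duration > 0)
  n_guide <- ceiling((duration - t0) / delta_t) + 2L
  gp <- sample_guideposts(w_bar, sigma, n_guide, seed)
  structure(list(w_bar = w_bar, sigma = rep_len(sigma, length(w_bar)),
                 guideposts = gp, delta_t = delta_t, t0 = t0),
            class = "liquid_schedule")
}

#' Synaptic strength at a time point
#'
#' Linear interpolation between the guideposts bracketing `t`; at a guidepost
#' time the strength equals the guidepost exactly. Before the schedule start
#' the strength is an error.
#'
#' @param schedule A `liquid_schedule`.
#' @param t Time (s), scalar.
#' @return Per-edge strength vector.
#' @export
strength_at <- function(schedule, t) {
  if (t < schedule$t0) abort("t precedes the schedule start")
  s <- (t - schedule$t0) / schedule$delta_t
  k <- floor(s)
  frac <- s - k
  K <- ncol(schedule$guideposts)
  if (k + 2 > K) abort("schedule does not cover t; rebuild with longer duration")
  a <- schedule$guideposts[, k + 1]
  b <- schedule$guideposts[, k + 2]
  ifelse(a == b, a, (1 - frac) * a + frac * b)
}
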