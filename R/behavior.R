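wrap_angle_deg <- function(a) {
  # map to (-180, 180]
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Per-cycle behavioral quantities of a trajectory
#'
#' Cuts a trajectory into locomotion cycles (period 4.2 s) and computes, for
#' each cycle: the turning bias (integral of the turning rate over the cycle,
#' degrees), the translational direction (angle of the displacement between
#' positions one cycle apart), the bearing (translational direction minus the
#' direction to the NaCl peak), the turning rate (bias per unit translational
#' distance, degrees/mm), and the concentration gradients along the
#' translational and normal (90 degrees counterclockwise) directions measured
#' by central finite differences at the cycle midpoint. Gradient columns are
#' also returned linearly normalized to \[-1, 1\] over the dataset.
#'
#' @param traj A `worm_trajectory` (or tibble with `t`, `x`, `y`, `phi`).
#' @param env Environment; defaults to the trajectory's own.
#' @param grad_eps Finite-difference half-step (cm).
#' @return Tibble with one row per complete cycle.
#' @export
cycle_series <- function(traj, env = attr(traj, "env"), grad_eps = 0.01) {
  stopifnot(!is.null(env))
  tt <- traj$t
  dt_rec <- tt[2] - tt[1]
  spc <- round(T_OSC / dt_rec)
  n_cyc <- (length(tt) - 1) %/% spc
  if (n_cyc < 2) abort("trajectory must span at least 2 locomotion cycles")

  i0 <- (seq_len(n_cyc) - 1L) * spc + 1L
  i1 <- i0 + spc
  bias <- vapply(seq_len(n_cyc), function(k) {
    sum(traj$phi[i0[k]:(i1[k] - 1L)]) * dt_rec
  }, numeric(1)) * 180 / pi

  dx <- traj$x[i1] - traj$x[i0]
  dy <- traj$y[i1] - traj$y[i0]
  trans_dir <- atan2(dy, dx)
  dist_mm <- sqrt(dx^2 + dy^2) * 10
  rate <- ifelse(dist_mm > 0, bias / dist_mm, NA_real_)

  im <- i0 + spc %/% 2L
  xm <- traj$x[im]
  ym <- traj$y[im]
  tm <- traj$t[im]

  if (env$kind == "isotropic") {
    bearing <- rep(NA_real_, n_cyc)
    tg <- ng <- rep(0, n_cyc)
  } else {
    to_peak <- atan2(env$peak[2] - ym, env$peak[1] - xm)
    bearing <- wrap_angle_deg((trans_dir - to_peak) * 180 / pi)
    ux <- cos(trans_dir)
    uy <- sin(trans_dir)
    tg <- (concentration(env, xm + grad_eps * ux, ym + grad_eps * uy, tm) -
             concentration(env, xm - grad_eps * ux, ym - grad_eps * uy, tm)) /
      (2 * grad_eps)
    # normal = translational rotated 90 degrees CCW
    ng <- (concentration(env, xm - grad_eps * uy, ym + grad_eps * ux, tm) -
             concentration(env, xm + grad_eps * uy, ym - grad_eps * ux, tm)) /
      (2 * grad_eps)
  }
  norm1 <- function(g) if (all(g == 0) || all(is.na(g))) g else g / max(abs(g), na.rm = TRUE)
  tibble(
    cycle = seq_len(n_cyc), t_mid = tm, x_mid = xm, y_mid = ym,
    turning_bias = bias, trans_dir = trans_dir, trans_dist_mm = dist_mm,
    turning_rate = rate, bearing = bearing,
    trans_grad = tg, normal_grad = ng,
    trans_grad_norm = norm1(tg), normal_grad_norm = norm1(ng)
  )
}

#' Binned turning-bias relationship curves
#'
#' Bins the per-cycle turning bias against bearing, normal gradient, and
#' translational gradient (normalized), returning per-bin mean, SD and count,
#' plus the sign-split means (average of positive and of negative biases in
#' the bin). Unoccupied bins have `NA` means, not zeros. Odd default bin
#' counts center a bin on zero.
#'
#' @param series Output of [cycle_series()].
#' @param n_bins_bearing Bins over (-180, 180\].
#' @param n_bins_gradient Bins over \[-1, 1\].
#' @return Long tibble: `panel`, `bin_mid`, `mean_bias`, `sd_bias`,
#'   `mean_pos`, `mean_neg`, `n`.
#' @export
relationship_curves <- function(series, n_bins_bearing = 13,
                                n_bins_gradient = 11) {
  one_panel <- function(x, y, breaks, panel) {
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
    out <- lapply(seq_along(mids), function(k) {
      yy <- y[!is.na(bin) & bin == k]
      tibble(panel = panel, bin_mid = mids[k],
             mean_bias = if (length(yy)) mean(yy) else NA_real_,
             sd_bias = if (length(yy) > 1) sd(yy) else NA_real_,
             mean_pos = if (any(yy > 0)) mean(yy[yy > 0]) else NA_real_,
             mean_neg = if (any(yy < 0)) mean(yy[yy < 0]) else NA_real_,
             n = length(yy))
    })
    dplyr::bind_rows(out)
  }
  dplyr::bind_rows(
    one_panel(series$bearing, series$turning_bias,
              seq(-180, 180, length.out = n_bins_bearing + 1), "bearing"),
    one_panel(series$normal_grad_norm, series$turning_bias,
              seq(-1, 1, length.out = n_bins_gradient + 1), "normal_gradient"),
    one_panel(series$trans_grad_norm, series$turning_bias,
              seq(-1, 1, length.out = n_bins_gradient + 1),
              "translational_gradient")
  )
}

#' Steering response to a concentration step at a given locomotion phase
#'
#' Runs the model in an isotropic environment until the oscillation has
#' settled, injects a single up- or down-step of the sensed concentration
#' change at the requested phase of the locomotion cycle, and quantifies the
#' steering response as the turning bias over the one cycle following the
#' stimulus. Down-step responses are deterministic; up-step responses are
#' stochastic (all-or-none ASEL triggering), so they are averaged over
#' `n_reps` repetitions.
#'
#' @param model A `worm_model`.
#' @param phase Locomotion phase in \[0, 2*pi) at which the step arrives.
#' @param step Signed scaled step (negative = down-step, positive = up-step,
#'   0 = no stimulus).
#' @param n_reps Repetitions (used for up-steps; down-steps run once).
#' @param settle_cycles Cycles simulated before the stimulus.
#' @param dt Integration step (s).
#' @param seed Integer seed.
#' @return One-row tibble: `phase`, `step`, `response` (mean turning bias,
#'   degrees), `response_sd`, `n`, `baseline` (unstimulated bias over the
#'   same cycle).
#' @export
steering_response <- function(model, phase, step, n_reps = 100,
                              settle_cycles = 20, dt = 0.01, seed = 1) {
  stopifnot(phase >= 0, phase < 2 * pi)
  env <- environment_isotropic()
  t_stim <- settle_cycles * T_OSC + phase / (2 * pi) * T_OSC
  duration <- (settle_cycles + 3) * T_OSC
  start <- list(x = 0, y = 0, theta = 0)

  bias_after <- function(traj) {
    w <- traj$t >= t_stim & traj$t < t_stim + T_OSC
    sum(traj$phi[w]) * dt * 180 / pi
  }
  base_traj <- simulate_run(model, env, duration = duration, dt = dt,
                            seed = seed, start = start)
  baseline <- bias_after(base_traj)
  if (step == 0) {
    return(tibble(phase = phase, step = 0, response = baseline,
                  response_sd = 0, n = 1L, baseline = baseline))
  }
  reps <- if (step > 0) n_reps else 1L
  vals <- vapply(seq_len(reps), function(r) {
    traj <- simulate_run(model, env, duration = duration, dt = dt,
                         seed = seed + r, start = start,
                         stimulus = list(time = t_stim, delta_c = step))
    bias_after(traj)
  }, numeric(1))
  tibble(phase = phase, step = step, response = mean(vals),
         response_sd = if (reps > 1) sd(vals) else 0,
         n = reps, baseline = baseline)
}

#' Random-walk statistics of turning-rate series
#'
#' Computes, per track, the mean and SD of the per-cycle turning rate and a
#' one-sample Kolmogorov-Smirnov P value against the reference normal
#' distribution; pooled lag correlations between the turning rate at a time
#' and the rate 6 s and 12 s later (rates interpolated between cycles); and
#' the 20 s strip decay table (strips grouped by initial-value bin, averaged
#' once per second).
#'
#' @param tracks A list of `worm_trajectory` objects, or a list of tibbles
#'   with columns `t` and `turning_rate` (one per track).
#' @param target_mu,target_sigma Reference normal parameters (degrees/mm).
#' @param lags Lag times (s).
#' @param strip_length Strip length (s) for the decay table.
#' @param decay_breaks Bin breaks (degrees/mm) on strips' initial values.
#' @return A `random_walk_stats` object with `per_track`, `lag`, and `decay`
#'   tibbles; see [tidy.random_walk_stats()].
#' @export
random_walk_stats <- function(tracks, target_mu = 0, target_sigma = 32.3,
                              lags = c(6, 12), strip_length = 20,
                              decay_breaks = seq(-90, 90, by = 30)) {
  if (length(tracks) == 0) abort("no tracks supplied")
  if (inherits(tracks, "data.frame")) tracks <- list(tracks)

  rate_series <- lapply(tracks, function(tr) {
    if (inherits(tr, "worm_trajectory")) {
      cs <- cycle_series(tr)
      tibble(t = cs$t_mid, turning_rate = cs$turning_rate)
    } else {
      stopifnot(all(c("t", "turning_rate") %in% names(tr)))
      tr[, c("t", "turning_rate")]
    }
  })

  per_track <- dplyr::bind_rows(lapply(seq_along(rate_series), function(i) {
    x <- rate_series[[i]]$turning_rate
    x <- x[is.finite(x)]
    if (length(x) < 3) abort(sprintf("track %d has fewer than 3 cycles", i))
    tibble(track = i, n_cycles = length(x), mu = mean(x), sigma = sd(x),
           ks_p = suppressWarnings(
             ks.test(x, "pnorm", target_mu, target_sigma)$p.value))
  }))

  lag_tbl <- dplyr::bind_rows(lapply(lags, function(L) {
    pairs <- lapply(rate_series, function(s) {
      ok <- s$t + L <= max(s$t)
      if (!any(ok)) return(NULL)
      later <- approx(s$t, s$turning_rate, xout = s$t[ok] + L)$y
      cbind(now = s$turning_rate[ok], later = later)
    })
    m <- do.call(rbind, pairs)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    tibble(lag = L,
           correlation = if (nrow(m) > 2) cor(m[, 1], m[, 2]) else NA_real_,
           n_pairs = nrow(m))
  }))

  decay <- dplyr::bind_rows(lapply(rate_series, function(s) {
    starts <- s$t[s$t + strip_length <= max(s$t)]
    if (length(starts) == 0) return(NULL)
    dplyr::bind_rows(lapply(starts, function(t0) {
      secs <- 0:strip_length
      vals <- approx(s$t, s$turning_rate, xout = t0 + secs)$y
      tibble(initial = vals[1], second = secs, rate = vals)
    }))
  }))
  if (nrow(decay) > 0) {
    decay$bin <- cut(decay$initial, decay_breaks, include.lowest = TRUE)
    decay <- decay |>
      dplyr::filter(!is.na(.data$bin), is.finite(.data$rate)) |>
      dplyr::group_by(.data$bin, .data$second) |>
      dplyr::summarise(mean_rate = mean(.data$rate), n = dplyr::n(),
                       .groups = "drop")
  }

  structure(list(per_track = per_track, lag = lag_tbl, decay = decay,
                 target_mu = target_mu, target_sigma = target_sigma),
            class = "random_walk_stats")
}

#' @export
print.random_walk_stats <- function(x, ...) {
  cat("<random_walk_stats>", nrow(x$per_track), "tracks\n")
  cat(sprintf("  mean mu = %.3f, mean sigma = %.3f deg/mm, mean K-S P = %.3f\n",
              mean(x$per_track$mu), mean(x$per_track$sigma),
              mean(x$per_track$ks_p)))
  for (i in seq_len(nrow(x$lag))) {
    cat(sprintf("  lag %g s correlation = %.3f\n",
                x$lag$lag[i], x$lag$correlation[i]))
  }
  invisible(x)
}

#' Simulated-ablation battery
#'
#' For each model and each named neuron set, ablates the set, simulates
#' `runs_per_model` runs, and records the mean chemotaxis index. The summary
#' averages the per-model means and reports their standard error, the
#' convention of grouped ablation figures.
#'
#' @param models List of `worm_model` objects.
#' @param neuron_sets Named list of character vectors (may include
#'   `character(0)` for the unablated control).
#' @param env An `env_spec`.
#' @param runs_per_model Simulated runs per (model, ablation) cell.
#' @param duration,dt Simulation settings (s).
#' @param liquid Optional per-edge SD vector passed to [simulate_run()]
#'   (applied to the *unablated* edge order; ablated models subset it).
#' @param seed Integer seed.
#' @return Tibble: `ablation`, `model`, `mean_ci`, `n_runs`; with a `summary`
#'   attribute tibble (`ablation`, `mean_ci`, `sem_ci`, `n_models`).
#' @export
ablation_battery <- function(models, neuron_sets, env, runs_per_model = 10,
                             duration = 800, dt = 0.01, liquid = NULL,
                             seed = 1) {
  stopifnot(length(models) >= 1, length(neuron_sets) >= 1)
  if (is.null(names(neuron_sets))) {
    names(neuron_sets) <- vapply(neuron_sets, function(s) {
      if (length(s) == 0) "none" else paste(s, collapse = "+")
    }, character(1))
  }
  withr_seed(seed, {
    run_seeds <- matrix(sample.int(.Machine$integer.max,
                                   length(models) * runs_per_model),
                        nrow = length(models))
  })
  rows <- list()
  for (a in names(neuron_sets)) {
    set <- neuron_sets[[a]]
    for (m in seq_along(models)) {
      mod <- models[[m]]
      sig <- liquid
      if (!is.null(sig)) sig <- rep_len(sig, nrow(mod$connectome$chem))
      if (length(set) > 0) {
        keep <- !(mod$connectome$chem$pre %in% set |
                    mod$connectome$chem$post %in% set)
        mod <- ablate(mod, set)
        if (!is.null(sig)) sig <- sig[keep]
      }
      cis <- vapply(seq_len(runs_per_model), function(r) {
        traj <- simulate_run(mod, env, duration = duration, dt = dt,
                             seed = run_seeds[m, r], liquid = sig,
                             record_every = 0)
        ci <- attr(traj, "ci")
        if (attr(traj, "diverged") || is.na(ci)) 0 else ci
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble(ablation = a, model = m,
                                         mean_ci = mean(cis),
                                         n_runs = runs_per_model)
    }
  }
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::group_by(.data$ablation) |>
    dplyr::summarise(
      mean_ci = mean(.data$mean_ci),
      sem_ci = sd(.data$mean_ci) / sqrt(dplyr::n()),
      n_models = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summ
  out
}

#' Overlay sharp turns (pirouettes) on a klinotaxis trajectory
#'
#' Post-hoc hook for the biased-random-walk strategy: once per locomotion
#' cycle a sharp turn occurs with probability `prob_fn(g)`, where `g` is the
#' temporal concentration gradient over the past cycle measured on the
#' modified track; the turn is an instantaneous heading change drawn from
#' `angle_sampler`. Between events the base klinotaxis dynamics are untouched:
#' the original displacement increments are rigidly rotated by the accumulated
#' turn angle. The probability equation and the turn-angle distribution are
#' user-supplied (fitted forms from behavioral experiments are not bundled).
#'
#' @param traj A `worm_trajectory`.
#' @param prob_fn Function of the temporal gradient (concentration/s)
#'   returning a probability in \[0, 1\]. `NULL` disables the overlay with a
#'   warning.
#' @param angle_sampler Function `(n)` returning turn angles in radians.
#' @param env Environment; defaults to the trajectory's own.
#' @param seed Integer seed.
#' @return The modified trajectory (positions, heading, concentration
#'   updated), with an `events` attribute tibble (`t`, `angle`).
#' @export
sharp_turn_overlay <- function(traj, prob_fn, angle_sampler,
                               env = attr(traj, "env"), seed = 1) {
  if (is.null(prob_fn)) {
    warn("no sharp-turn probability function supplied; overlay disabled")
    return(traj)
  }
  stopifnot(!is.null(env), is.function(angle_sampler))
  tt <- traj$t
  dt_rec <- tt[2] - tt[1]
  spc <- round(T_OSC / dt_rec)
  n <- length(tt)

  x <- traj$x
  y <- traj$y
  theta <- traj$theta
  rot <- 0
  anchor <- 1L
  events <- list()
  withr_seed(seed, {
    k <- 1L
    while ((k + 1L) * spc + 1L <= n + spc) {
      i_end <- min(k * spc + 1L, n)
      i_start <- (k - 1L) * spc + 1L
      if (rot != 0) {
        idx <- (anchor + 1L):i_end
        dx <- traj$x[idx] - traj$x[anchor]
        dy <- traj$y[idx] - traj$y[anchor]
        x[idx] <- x[anchor] + cos(rot) * dx - sin(rot) * dy
        y[idx] <- y[anchor] + sin(rot) * dx + cos(rot) * dy
        theta[idx] <- traj$theta[idx] + rot
      }
      g <- (concentration(env, x[i_end], y[i_end], tt[i_end]) -
              concentration(env, x[i_start], y[i_start], tt[i_start])) / T_OSC
      if (runif(1) < prob_fn(g)) {
        ang <- angle_sampler(1)
        rot <- rot + ang
        anchor <- i_end
        events[[length(events) + 1]] <- tibble(t = tt[i_end], angle = ang)
      }
      if (i_end == n) break
      k <- k + 1L
    }
  })
  out <- traj
  out$x <- x
  out$y <- y
  out$theta <- theta
  out$C <- concentration(env, x, y, tt)
  attr(out, "events") <- if (length(events)) dplyr::bind_rows(events) else
    tibble(t = numeric(), angle = numeric())
  out
}
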