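#' Simulate one run of the worm model
#'
#' Integrates the coupled sensory-network-kinematics system with forward Euler
#' at fixed `dt` and returns the trajectory as a tibble. With `liquid` set,
#' the chemical synapse strengths follow the stochastic piecewise-linear
#' liquid-synapse process; with `liquid = NULL` they stay at their evolved
#' values. The run is fully determined by `(model, env, seed, arguments)`.
#'
#' @param model A `worm_model` from [decode_genome()] (possibly ablated).
#' @param env An `env_spec`.
#' @param duration Simulated time (s).
#' @param dt Integration step (s).
#' @param seed Integer seed; drives ASEL trigger noise, the liquid guideposts,
#'   and the random initial heading.
#' @param start Optional list with `x`, `y`, `theta`. Defaults to a point
#'   `start_radius` cm from the NaCl peak along +x with a uniform-random
#'   heading.
#' @param start_radius Initial distance from the peak (cm).
#' @param liquid `NULL` for fixed weights, a numeric per-chemical-edge SD
#'   vector (recycled), or a prebuilt [liquid_schedule()].
#' @param record_every Keep every `record_every`-th step in the trajectory
#'   (1 = every step). The chemotaxis index is always computed at full `dt`
#'   resolution internally.
#' @param record_voltages Also return the full voltage matrix.
#' @param stimulus Optional `list(time =, delta_c =)`: overrides the sensed
#'   concentration change for the single step covering `time` (used by
#'   steering-response assays).
#' @param capture_radius Radius (cm) defining "reached the peak".
#' @param c_scale Sensory calibration constant; default [delta_c_scale()].
#' @return A `worm_trajectory` tibble with columns `t`, `x`, `y`, `theta`,
#'   `phi`, `C`, `dC`, the four motor outputs, `V_ASEL`, `V_ASER`, and
#'   attributes `ci`, `captured`, `min_r`, `diverged`, `env`, `seed`.
#' @export
simulate_run <- function(model, env, duration = 800, dt = 0.01, seed = 1,
                         start = NULL, start_radius = 4.5, liquid = NULL,
                         record_every = 1, record_voltages = FALSE,
                         stimulus = NULL, capture_radius = 0.1,
                         c_scale = NULL) {
  stopifnot(inherits(model, "worm_model"), inherits(env, "env_spec"),
            duration > 0, dt > 0)
  con <- model$connectome
  roster <- con$neurons
  idx <- function(nm) match(nm, roster) - 1L

  if (is.null(start)) {
    withr_seed(bitwXor(as.integer(seed), 779468L),
               theta0 <- runif(1, 0, 2 * pi))
    start <- list(x = env$peak[1] + start_radius, y = env$peak[2],
                  theta = theta0)
  }
  c_scale <- c_scale %||% delta_c_scale(env, dt)

  # chemical weight guideposts: one column = fixed weights
  if (is.null(liquid)) {
    gp <- matrix(model$w_c, ncol = 1)
    delta_t <- 12
    t0 <- 0
  } else if (inherits(liquid, "liquid_schedule")) {
    gp <- liquid$guideposts
    delta_t <- liquid$delta_t
    t0 <- liquid$t0
  } else {
    sched <- liquid_schedule(model$w_c, liquid, duration,
                             seed = bitwXor(as.integer(seed), 335477L))
    gp <- sched$guideposts
    delta_t <- sched$delta_t
    t0 <- sched$t0
  }

  env_par <- switch(env$kind,
    isotropic = env$level,
    conical = c(env$kappa, env$r_max, as.numeric(isTRUE(env$literal))),
    gaussian = c(env$N0, env$D_c, env$d_c, env$t0_env)
  )
  env_kind <- match(env$kind, c("isotropic", "conical", "gaussian")) - 1L

  ablated <- as.integer(roster %in% (attr(con, "ablated") %||% character()))
  osc_sign <- numeric(length(roster))
  osc_sign[roster %in% DORSAL_MOTOR] <- 1
  osc_sign[roster %in% VENTRAL_MOTOR] <- -1

  sens <- model$sensory
  sens_vec <- c(sens$tau_R, sens$beta_R, sens$tau_alphaR, sens$gamma_R,
                sens$E_R_ext, sens$tau_L, sens$beta_L, sens$tau_alphaL,
                sens$gamma_L, sens$E_L_Ca, sens$in_thres, sens$xi_range)

  withr_seed(seed, {
    res <- sim_run_cpp(
      chem_pre = idx(con$chem$pre), chem_post = idx(con$chem$post),
      chem_E = model$E,
      gap_a = idx(con$gap$a), gap_b = idx(con$gap$b), gap_w = model$w_g,
      chem_guideposts = gp, liquid_delta_t = delta_t, liquid_t0 = t0,
      b = unname(model$b), tau = unname(model$tau), osc_sign = osc_sign,
      w_osc = model$w_osc, w_nmj = model$w_nmj,
      dorsal_idx = idx(DORSAL_MOTOR), ventral_idx = idx(VENTRAL_MOTOR),
      sensory = sens_vec, ablated = ablated,
      env_kind = env_kind, env_par = env_par, c_scale = c_scale,
      peak_x = env$peak[1], peak_y = env$peak[2],
      x0 = start$x, y0 = start$y, theta0 = start$theta,
      duration = duration, dt = dt, speed = V_SPEED,
      record_every = as.integer(record_every),
      stim_time = if (is.null(stimulus)) -1 else stimulus$time,
      stim_dc = if (is.null(stimulus)) 0 else stimulus$delta_c,
      capture_radius = capture_radius,
      record_voltages = record_voltages
    )
  })

  traj <- as_tibble(as.data.frame(res$traj))
  names(traj) <- c("t", "x", "y", "theta", "phi", "C", "dC",
                   "out_SMBDL", "out_SMBDR", "out_SMBVL", "out_SMBVR",
                   "V_ASEL", "V_ASER")
  if (res$diverged) {
    warn(sprintf("simulation diverged at t = %.2f s; trajectory truncated",
                 res$t_end))
  }
  structure(traj,
            class = c("worm_trajectory", class(traj)),
            ci = res$ci, captured = res$captured, min_r = res$min_r,
            diverged = res$diverged, r0 = res$r0, env = env, seed = seed,
            dt = dt, record_every = record_every,
            voltages = if (record_voltages) {
              v <- as.data.frame(res$volts)
              names(v) <- roster
              as_tibble(v)
            })
}

#' Write a trajectory and its run manifest
#'
#' @param traj A `worm_trajectory`.
#' @param path Output CSV path; a JSON manifest is written alongside.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  env <- attr(traj, "env")
  manifest <- list(
    seed = attr(traj, "seed"), dt = attr(traj, "dt"),
    env = unclass(env), ci = attr(traj, "ci"),
    captured = attr(traj, "captured"), min_r = attr(traj, "min_r"),
    diverged = attr(traj, "diverged")
  )
  jsonlite::write_json(manifest, paste0(tools::file_path_sans_ext(path), "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
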