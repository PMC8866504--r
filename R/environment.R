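#' NaCl environment models
#'
#' Three concentration fields are supported:
#'
#' * **conical**: gradient magnitude `kappa` everywhere, independent of
#'   position. By default the field is `C = kappa * (r_max - d)` (clipped at
#'   zero), where `d` is distance to the NaCl peak, so the placement point is
#'   the concentration maximum. Setting `literal = TRUE` instead uses the
#'   increasing-with-distance form `C = kappa * sqrt(x^2 + y^2)`, which has its
#'   minimum at the origin; both share the constant-gradient property.
#' * **gaussian**: borderless 2D diffusion from a point deposit of `N0` on an
#'   agar plate of thickness `d_c` with diffusion coefficient `D_c`, started
#'   `t0_env` seconds before the experiment:
#'   `C = N0 / (4 pi d_c D_c (t + t0_env)) * exp(-d^2 / (400 D_c (t + t0_env)))`.
#' * **isotropic**: spatially constant, so the sensed concentration change is
#'   identically zero; used for random-walk assays.
#'
#' Default gaussian constants are chosen so the concentration span across the
#' 4.5 cm start radius is comparable to the conical field's span, giving the
#' two environments a similar sensory dynamic range.
#'
#' @param kappa Conical gradient coefficient (concentration per cm).
#' @param peak NaCl placement point `c(x, y)` in cm.
#' @param r_max Radius (cm) at which the default conical field reaches zero.
#' @param literal Use the literal increasing-with-distance conical form.
#' @param N0 Deposited NaCl amount (gaussian).
#' @param D_c Diffusion coefficient (cm^2/s).
#' @param d_c Agar thickness (cm).
#' @param t0_env Pre-diffusion time (s) before the run starts.
#' @param level Constant concentration of the isotropic field.
#' @return An `env_spec` object.
#' @name environments
NULL

#' @rdname environments
#' @export
environment_conical <- function(kappa = 1, peak = c(0, 0), r_max = 6,
                                literal = FALSE) {
  stopifnot(kappa > 0, r_max > 0, length(peak) == 2)
  structure(list(kind = "conical", kappa = kappa, peak = peak,
                 r_max = r_max, literal = literal),
            class = "env_spec")
}

#' @rdname environments
#' @export
environment_gaussian <- function(N0 = 0.55, D_c = 1e-5, d_c = 0.2,
                                 t0_env = 3600, peak = c(0, 0)) {
  stopifnot(N0 > 0, D_c > 0, d_c > 0, t0_env > 0, length(peak) == 2)
  structure(list(kind = "gaussian", N0 = N0, D_c = D_c, d_c = d_c,
                 t0_env = t0_env, peak = peak),
            class = "env_spec")
}

#' @rdname environments
#' @export
environment_isotropic <- function(level = 1) {
  structure(list(kind = "isotropic", level = level, peak = c(0, 0)),
            class = "env_spec")
}

#' @export
print.env_spec <- function(x, ...) {
  cat("<env_spec>", x$kind, "\n")
  invisible(x)
}

#' Concentration field value
#'
#' @param env An `env_spec`.
#' @param x,y Position (cm); vectorized.
#' @param t Time since run start (s).
#' @return Concentration in model units.
#' @export
concentration <- function(env, x, y, t = 0) {
  switch(env$kind,
    isotropic = rep_len(env$level, max(length(x), length(y))),
    conical = {
      if (isTRUE(env$literal)) {
        env$kappa * sqrt(x^2 + y^2)
      } else {
        d <- sqrt((x - env$peak[1])^2 + (y - env$peak[2])^2)
        env$kappa * pmax(env$r_max - d, 0)
      }
    },
    gaussian = {
      r2 <- (x - env$peak[1])^2 + (y - env$peak[2])^2
      tt <- t + env$t0_env
      env$N0 / (4 * pi * env$d_c * env$D_c * tt) * exp(-r2 / (400 * env$D_c * tt))
    },
    abort("unknown environment kind")
  )
}

#' Calibration constant for the sensed concentration change
#'
#' The sensory signal is the per-step concentration change divided by
#' `c_scale` and clipped to \[-1, 1\]. `c_scale` defaults to the largest
#' per-step change achievable at crawling speed `v` in the steepest region of
#' the environment, so straight radial motion saturates the signal.
#'
#' @param env An `env_spec`.
#' @param dt Integration step (s).
#' @param v Crawling speed (cm/s).
#' @return Positive scalar (isotropic fields return 1; the signal is zero
#'   anyway).
#' @export
delta_c_scale <- function(env, dt = 0.01, v = V_SPEED) {
  switch(env$kind,
    isotropic = 1,
    conical = env$kappa * v * dt,
    gaussian = {
      grad <- function(r) {
        tt <- env$t0_env
        base <- env$N0 / (4 * pi * env$d_c * env$D_c * tt)
        base * exp(-r^2 / (400 * env$D_c * tt)) * (2 * r / (400 * env$D_c * tt))
      }
      opt <- stats::optimize(grad, c(1e-6, 10 * env$t0_env^0.5), maximum = TRUE)
      opt$objective * v * dt
    }
  )
}

#' Sensed concentration change along a trajectory tail
#'
#' @param env An `env_spec`.
#' @param x,y,t Two or more trailing samples of position and time (last element
#'   is "now").
#' @param c_scale Calibration constant, see [delta_c_scale()].
#' @return Scaled, clipped concentration change in \[-1, 1\].
#' @export
sense_delta_c <- function(env, x, y, t, c_scale) {
  n <- length(x)
  if (n < 2) abort("need at least two trajectory samples to sense a change")
  c_now <- concentration(env, x[n], y[n], t[n])
  c_prev <- concentration(env, x[n - 1], y[n - 1], t[n - 1])
  max(-1, min(1, (c_now - c_prev) / c_scale))
}

#' One Euler step of the point-agent kinematics
#'
#' Position advances along the current heading at constant speed; the turning
#' rate is the neuromuscular coupling times the dorsal-minus-ventral sum of
#' motor neuron outputs.
#'
#' @param agent Named list or vector with `x`, `y`, `theta`.
#' @param motor_outputs Length-4 outputs in (0, 1), ordered
#'   SMBDL, SMBDR, SMBVL, SMBVR.
#' @param w_nmj Neuromuscular coupling strength (rad/s per unit output).
#' @param dt Step (s).
#' @param v Speed (cm/s).
#' @return Updated list with `x`, `y`, `theta`, `phi`.
#' @export
step_kinematics <- function(agent, motor_outputs, w_nmj, dt, v = V_SPEED) {
  stopifnot(length(motor_outputs) == 4)
  phi <- w_nmj * (motor_outputs[1] + motor_outputs[2] -
                    motor_outputs[3] - motor_outputs[4])
  list(
    x = agent$x + dt * v * cos(agent$theta),
    y = agent$y + dt * v * sin(agent$theta),
    theta = agent$theta + dt * phi,
    phi = phi
  )
}
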