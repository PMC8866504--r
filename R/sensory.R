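#' Rate constants of the ASE sensory neuron model
#'
#' ASER is a graded OFF-cell: concentration decreases set its stimulus rate
#' variable, opening channels whose conductance saturates through
#' `tanh(gamma_R * h)`, so the depolarization peak is a saturating function of
#' the down-step size. ASEL is a stochastic all-or-none ON-cell: an increase
#' only triggers depolarization when the integrated signal
#' `delta_c + net_L + xi` exceeds `in_thres`, where `xi` is uniform noise;
#' once triggered the gate variable is set to 1 regardless of step size, so
#' the amplitude is stimulus-invariant while the triggering probability grows
#' with the step.
#'
#' Defaults are calibrated once so that small up-steps trigger rarely and
#' near-saturating up-steps trigger almost surely, and so that both neurons
#' show a fast rise and slow decay. All values are overridable.
#'
#' @param tau_R,tau_L Membrane time constants (s).
#' @param beta_R,beta_L Channel closing rates (1/s); the slow-decay scale.
#' @param tau_alphaR,tau_alphaL Decay time constants of the stimulus rate
#'   variables (s).
#' @param gamma_R,gamma_L Conductance gains inside the `tanh` saturation.
#' @param E_R_ext Chemosensory reversal potential of ASER.
#' @param E_L_Ca Calcium reversal potential of ASEL.
#' @param in_thres Activation threshold of ASEL's integrated signal.
#' @param xi_range Half-width of ASEL's uniform trigger noise.
#' @return Named list of parameters.
#' @export
sensory_params <- function(tau_R = 0.1, beta_R = 0.1, tau_alphaR = 1,
                           gamma_R = 2, E_R_ext = 1,
                           tau_L = 0.1, beta_L = 0.1, tau_alphaL = 1,
                           gamma_L = 2, E_L_Ca = 1,
                           in_thres = 0.5, xi_range = 0.3) {
  p <- list(tau_R = tau_R, beta_R = beta_R, tau_alphaR = tau_alphaR,
            gamma_R = gamma_R, E_R_ext = E_R_ext,
            tau_L = tau_L, beta_L = beta_L, tau_alphaL = tau_alphaL,
            gamma_L = gamma_L, E_L_Ca = E_L_Ca,
            in_thres = in_thres, xi_range = xi_range)
  if (any(unlist(p[c("tau_R", "tau_L", "tau_alphaR", "tau_alphaL")]) <= 0)) {
    abort("time constants must be positive")
  }
  if (gamma_R <= 0 || gamma_L <= 0) abort("gamma parameters must be positive")
  if (in_thres <= 0 || in_thres > 2) abort("in_thres must lie in (0, 2]")
  if (xi_range < 0) abort("xi_range must be non-negative")
  p
}

#' Resting states of the sensory neurons
#'
#' Channels are closed at rest: the closed-state occupancy `u` is 1, the open
#' gate `h` is 0 (their sum is conserved at 1), the stimulus rate variable is
#' 0 and the voltage sits at the resting potential 0.
#'
#' @return Named list state.
#' @name sensory_state
NULL

#' @rdname sensory_state
#' @export
aser_state <- function() list(V = 0, u = 1, h = 0, alpha = 0, g = 0)

#' @rdname sensory_state
#' @export
asel_state <- function() list(V = 0, u = 1, h = 0, alpha = 0, g = 0, xi = 0)

check_sensory_inputs <- function(state, delta_c) {
  if (any(!is.finite(unlist(state)))) abort("non-finite sensory state")
  if (!is.finite(delta_c) || delta_c < -1 || delta_c > 1) {
    abort(sprintf("delta_c must lie in [-1, 1], got %s", format(delta_c)))
  }
}

#' One Euler step of the ASER (graded OFF-cell) dynamics
#'
#' The update order is: membrane voltage (using the conductance carried in the
#' state), then the stimulus rate variable (`alpha = -delta_c` while the
#' concentration falls, exponential decay otherwise), then the channel states
#' `u`/`h` with their sum conserved exactly, then the conductance
#' `g = tanh(gamma_R * h)`.
#'
#' @param state ASER state from [aser_state()].
#' @param delta_c Scaled concentration change in \[-1, 1\].
#' @param afferent_chem_current,afferent_gap_current Summed synaptic current
#'   terms from other neurons, already evaluated at the current state (0 for a
#'   standalone neuron).
#' @param params From [sensory_params()].
#' @param dt Step (s).
#' @return Updated state.
#' @export
step_aser <- function(state, delta_c, afferent_chem_current = 0,
                      afferent_gap_current = 0, params = sensory_params(),
                      dt = 0.01) {
  stopifnot(dt > 0)
  check_sensory_inputs(state, delta_c)
  dV <- (-state$V + afferent_chem_current + afferent_gap_current -
           state$g * (state$V - params$E_R_ext)) / params$tau_R
  alpha <- if (delta_c < 0) -delta_c else {
    state$alpha + dt * (-state$alpha / params$tau_alphaR)
  }
  du <- -alpha * state$u + params$beta_R * state$h
  u <- state$u + dt * du
  h <- state$h - dt * du
  list(V = state$V + dt * dV, u = u, h = h, alpha = alpha,
       g = tanh(params$gamma_R * h))
}

#' One Euler step of the ASEL (all-or-none ON-cell) dynamics
#'
#' While the concentration increases, a fresh uniform noise value is drawn
#' each step and the gate opens (`alpha = 1`) whenever
#' `delta_c + net_L + xi > in_thres`; otherwise `alpha` decays. Because the
#' triggered `alpha` is always exactly 1, the depolarization amplitude does
#' not depend on the step size -- only the triggering probability does. The
#' membrane has no direct synaptic current (afferents act only through the
#' trigger), and the voltage relaxes toward `E_L_Ca` through the calcium
#' conductance, so it never exceeds that bound.
#'
#' @param state ASEL state from [asel_state()].
#' @param delta_c Scaled concentration change in \[-1, 1\].
#' @param net_L Bounded afferent signal from [asel_afferent()], in (-1, 1).
#' @param params From [sensory_params()].
#' @param dt Step (s).
#' @return Updated state (with the noise value used stored in `xi`).
#' @export
step_asel <- function(state, delta_c, net_L = 0, params = sensory_params(),
                      dt = 0.01) {
  stopifnot(dt > 0)
  check_sensory_inputs(state, delta_c)
  if (!is.finite(net_L) || abs(net_L) >= 1) {
    abort("net_L must be a tanh-bounded signal in (-1, 1)")
  }
  dV <- (-state$V - state$g * (state$V - params$E_L_Ca)) / params$tau_L
  xi <- state$xi
  if (delta_c > 0) {
    xi <- runif(1, -params$xi_range, params$xi_range)
    in_L <- delta_c + net_L + xi
    alpha <- if (in_L > params$in_thres) 1 else {
      state$alpha + dt * (-state$alpha / params$tau_alphaL)
    }
  } else {
    alpha <- state$alpha + dt * (-state$alpha / params$tau_alphaL)
  }
  du <- -alpha * state$u + params$beta_L * state$h
  u <- state$u + dt * du
  h <- state$h - dt * du
  list(V = state$V + dt * dV, u = u, h = h, alpha = alpha,
       g = tanh(params$gamma_L * h), xi = xi)
}

#' Bounded afferent signal into ASEL
#'
#' Sums the chemical and electrical synaptic currents from presynaptic neurons
#' onto ASEL and bounds the total with `tanh`, so the trigger contribution
#' always lies strictly inside (-1, 1).
#'
#' @param voltages Named per-neuron voltage vector (roster names).
#' @param model A `worm_model` (provides edges, weights, biases).
#' @param V_L Current ASEL voltage.
#' @return Scalar in (-1, 1).
#' @export
asel_afferent <- function(voltages, model, V_L = voltages[["ASEL"]]) {
  if (any(!is.finite(voltages))) abort("non-finite presynaptic voltage")
  con <- model$connectome
  idx <- which(con$chem$post == "ASEL")
  chem <- 0
  if (length(idx) > 0) {
    pre <- con$chem$pre[idx]
    f <- neuron_output(voltages[pre], model$b[pre])
    chem <- -sum(model$w_c[idx] * f * (V_L - model$E[idx]))
  }
  gidx <- which(con$gap$a == "ASEL" | con$gap$b == "ASEL")
  gap <- 0
  if (length(gidx) > 0) {
    other <- ifelse(con$gap$a[gidx] == "ASEL", con$gap$b[gidx], con$gap$a[gidx])
    gap <- -sum(model$w_g[gidx] * (V_L - voltages[other]))
  }
  tanh(chem + gap)
}

#' Run a concentration step-stimulus protocol on one sensory neuron
#'
#' Reproduces the standard characterization protocol: from rest, a single
#' instantaneous concentration step (scaled magnitude `step`) is applied at
#' `onset`, and the voltage trace is recorded. Up-steps drive ASEL (repeated
#' `n_reps` times since triggering is stochastic); down-steps drive ASER
#' (deterministic). A small optional Gaussian voltage noise can be added to
#' separate overlapping traces in plots; it defaults to off.
#'
#' @param neuron `"ASEL"` or `"ASER"`.
#' @param steps Scaled step magnitudes (positive for ASEL, negative for ASER).
#' @param n_reps Repetitions per step magnitude.
#' @param onset Stimulus onset time (s).
#' @param duration Trace duration (s).
#' @param dt Step (s).
#' @param seed Integer seed.
#' @param params From [sensory_params()].
#' @param voltage_noise_sd SD of cosmetic additive voltage noise (default 0).
#' @param out_dir Optional directory; when given, per-trial traces and the
#'   peak summary are written as CSV.
#' @return List with `traces` (tibble: `step`, `rep`, `t`, `V`, `g`, `alpha`)
#'   and `peaks` (tibble: `step`, `rep`, `peak`, `activated`, `t_peak`).
#' @export
run_step_protocol <- function(neuron = c("ASEL", "ASER"), steps, n_reps = 50,
                              onset = 2, duration = 30, dt = 0.01, seed = 1,
                              params = sensory_params(), voltage_noise_sd = 0,
                              out_dir = NULL) {
  neuron <- match.arg(neuron)
  if (neuron == "ASEL" && any(steps <= 0)) abort("ASEL protocol needs up-steps (> 0)")
  if (neuron == "ASER" && any(steps >= 0)) abort("ASER protocol needs down-steps (< 0)")
  n_steps <- floor(duration / dt)
  onset_i <- max(1L, round(onset / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1)

  traces <- list()
  peaks <- list()
  withr_seed(seed, {
    for (s in steps) {
      for (r in seq_len(n_reps)) {
        st <- if (neuron == "ASEL") asel_state() else aser_state()
        V <- g <- al <- numeric(n_steps + 1)
        for (i in seq_len(n_steps)) {
          dc <- if (i == onset_i) s else 0
          st <- if (neuron == "ASEL") {
            step_asel(st, dc, 0, params, dt)
          } else {
            step_aser(st, dc, 0, 0, params, dt)
          }
          V[i + 1] <- st$V + if (voltage_noise_sd > 0) rnorm(1, 0, voltage_noise_sd) else 0
          g[i + 1] <- st$g
          al[i + 1] <- st$alpha
        }
        traces[[length(traces) + 1]] <-
          tibble(step = s, rep = r, t = times, V = V, g = g, alpha = al)
        pk <- which.max(abs(V))
        peaks[[length(peaks) + 1]] <-
          tibble(step = s, rep = r, peak = V[pk], t_peak = times[pk],
                 activated = max(abs(V)) > 1e-3)
      }
    }
  })
  traces <- dplyr::bind_rows(traces)
  peaks <- dplyr::bind_rows(peaks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(traces, file.path(out_dir, paste0(tolower(neuron), "_traces.csv")),
                     row.names = FALSE)
    utils::write.csv(peaks, file.path(out_dir, paste0(tolower(neuron), "_peaks.csv")),
                     row.names = FALSE)
  }
  list(traces = traces, peaks = peaks)
}
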