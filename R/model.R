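#' Graded synaptic output of a neuron
#'
#' Logistic sigmoid of the membrane voltage plus bias; strictly increasing in
#' the voltage and saturating at 0 and 1. Strongly negative biases park a
#' neuron deep in the lower saturated region, where its output barely responds
#' to input changes.
#'
#' @param v Membrane voltage (relative to rest).
#' @param b Bias.
#' @return Output in (0, 1); vectorized.
#' @export
neuron_output <- function(v, b = 0) {
  stats::plogis(v + b)
}

#' Right-hand side of the network voltage dynamics
#'
#' For every non-sensory neuron `i`:
#' `tau_i dV_i/dt = -V_i - sum_j w_c f(V_j + b_j)(V_i - E_ij)
#'  - sum_j w_g (V_i - V_j) + delta_i I_osc(t)`,
#' where the chemical term drives the voltage toward the edge's reversal
#' potential, the gap term is symmetric ohmic coupling, and SMB motor neurons
#' receive the sinusoidal oscillator input (dorsal `+`, ventral `-` phase).
#' Sensory neurons act as presynaptic sources; their own derivative entries
#' are returned as zero (their dynamics are governed by the ASE equations).
#'
#' @param V Named voltage vector over the roster.
#' @param model A `worm_model`.
#' @param t Time (s), used by the oscillator.
#' @param oscillator Include the oscillator drive?
#' @param chem_w Optional chemical weight vector overriding `model$w_c`
#'   (used by time-varying liquid synapses).
#' @return Named derivative vector `dV/dt`.
#' @export
network_derivative <- function(V, model, t = 0, oscillator = TRUE,
                               chem_w = NULL) {
  con <- model$connectome
  roster <- con$neurons
  w_c <- chem_w %||% model$w_c
  f <- neuron_output(V[con$chem$pre], model$b[con$chem$pre])
  abl <- attr(con, "ablated")
  if (length(abl)) f[con$chem$pre %in% abl] <- 0

  dV <- setNames(numeric(length(roster)), roster)
  chem_cur <- -w_c * f * (V[con$chem$post] - model$E)
  for (k in seq_along(chem_cur)) {
    dV[con$chem$post[k]] <- dV[con$chem$post[k]] + chem_cur[k]
  }
  gap_cur_a <- -model$w_g * (V[con$gap$a] - V[con$gap$b])
  for (k in seq_len(nrow(con$gap))) {
    dV[con$gap$a[k]] <- dV[con$gap$a[k]] + gap_cur_a[k]
    dV[con$gap$b[k]] <- dV[con$gap$b[k]] - gap_cur_a[k]
  }
  if (oscillator) {
    osc <- model$w_osc * sin(2 * pi * t / T_OSC)
    dV[DORSAL_MOTOR] <- dV[DORSAL_MOTOR] + osc
    dV[VENTRAL_MOTOR] <- dV[VENTRAL_MOTOR] - osc
  }
  dV <- (dV - V) / model$tau
  dV[SENSORY_NEURONS] <- 0
  if (length(abl)) dV[abl] <- 0
  dV
}

#' Relax the network to its fixed point
#'
#' Integrates the voltage dynamics from rest (all zeros) with the same
#' semi-implicit update as the simulator (the equation is linear in the
#' voltage given the presynaptic outputs, so the conductance terms are
#' treated implicitly; unconditionally stable, identical fixed points) until
#' the derivative norm drops below `tol`, giving the steady state of the
#' network in the absence of sensory input (and, by default, of the
#' oscillator, which has no fixed point when active).
#'
#' @param model A `worm_model`.
#' @param with_oscillator Include the oscillator drive (the state then keeps
#'   integrating and the relaxation will report non-convergence).
#' @param dt Integration step (s).
#' @param tol Convergence tolerance on `max |dV/dt|`.
#' @param max_time Give up after this much simulated time (s).
#' @return Named voltage vector with attribute `converged`.
#' @export
steady_state <- function(model, with_oscillator = FALSE, dt = 0.01,
                         tol = 1e-9, max_time = 2000) {
  roster <- model$connectome$neurons
  con <- model$connectome
  abl <- attr(con, "ablated") %||% character()
  V <- setNames(numeric(length(roster)), roster)
  t <- 0
  repeat {
    dV <- network_derivative(V, model, t, oscillator = with_oscillator)
    if (max(abs(dV)) < tol) {
      attr(V, "converged") <- TRUE
      return(V)
    }
    # semi-implicit step: conductance sums from the current outputs
    f <- neuron_output(V[con$chem$pre], model$b[con$chem$pre])
    if (length(abl)) f[con$chem$pre %in% abl] <- 0
    S_w <- S_wE <- S_g <- S_gV <- setNames(numeric(length(roster)), roster)
    wf <- model$w_c * f
    for (k in seq_along(wf)) {
      p <- con$chem$post[k]
      S_w[p] <- S_w[p] + wf[k]
      S_wE[p] <- S_wE[p] + wf[k] * model$E[k]
    }
    for (k in seq_len(nrow(con$gap))) {
      a <- con$gap$a[k]
      b <- con$gap$b[k]
      S_g[a] <- S_g[a] + model$w_g[k]
      S_gV[a] <- S_gV[a] + model$w_g[k] * V[b]
      S_g[b] <- S_g[b] + model$w_g[k]
      S_gV[b] <- S_gV[b] + model$w_g[k] * V[a]
    }
    drive <- S_wE + S_gV
    if (with_oscillator) {
      osc <- model$w_osc * sin(2 * pi * t / T_OSC)
      drive[DORSAL_MOTOR] <- drive[DORSAL_MOTOR] + osc
      drive[VENTRAL_MOTOR] <- drive[VENTRAL_MOTOR] - osc
    }
    a_ <- dt / model$tau
    Vn <- (V + a_ * drive) / (1 + a_ * (1 + S_w + S_g))
    Vn[SENSORY_NEURONS] <- V[SENSORY_NEURONS]
    if (length(abl)) Vn[abl] <- 0
    V <- Vn
    t <- t + dt
    if (!all(is.finite(V))) {
      abort("network diverged during steady-state relaxation")
    }
    if (t > max_time) {
      warn(sprintf("steady state not reached within %g s (max |dV/dt| = %.3g)",
                   max_time, max(abs(dV))))
      attr(V, "converged") <- FALSE
      return(V)
    }
  }
}
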