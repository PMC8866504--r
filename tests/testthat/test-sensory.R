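# reference integration of the standalone ASER system with deSolve at high
# accuracy: after a down-step of size |dc| the rate variable starts at |dc|
# and decays smoothly, so the whole system is a smooth ODE
aser_oracle_peak <- function(dc, params = sensory_params(), t_max = 40) {
  rhs <- function(t, y, p) {
    g <- tanh(p$gamma_R * y["h"])
    du <- -y["alpha"] * y["u"] + p$beta_R * y["h"]
    list(c(
      V = unname((-y["V"] - g * (y["V"] - p$E_R_ext)) / p$tau_R),
      u = unname(du),
      h = unname(-du),
      alpha = unname(-y["alpha"] / p$tau_alphaR)
    ))
  }
  y0 <- c(V = 0, u = 1, h = 0, alpha = abs(dc))
  out <- deSolve::ode(y0, seq(0, t_max, by = 0.001), rhs, params,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  max(out[, "V"])
}

run_aser_trace <- function(dc, dt = 0.01, duration = 40,
                           params = sensory_params()) {
  st <- aser_state()
  n <- floor(duration / dt)
  V <- numeric(n + 1)
  for (i in seq_len(n)) {
    st <- step_aser(st, if (i == 1) dc else 0, 0, 0, params, dt)
    V[i + 1] <- st$V
  }
  V
}

test_that("ASER is an OFF-cell and ASEL an ON-cell", {
  # arbitrary non-negative stimulus sequence never moves ASER off rest
  st <- aser_state()
  dcs <- c(0, 0.5, 1, 0.2, 0, 0.9)
  for (k in 1:300) st <- step_aser(st, dcs[k %% 6 + 1], 0, 0, dt = 0.01)
  expect_identical(st$V, 0)
  expect_identical(st$h, 0)

  # non-positive sequence never depolarizes ASEL
  st <- asel_state()
  for (k in 1:300) st <- step_asel(st, -dcs[k %% 6 + 1], 0, dt = 0.01)
  expect_identical(st$V, 0)
})

test_that("ASEL never activates when the threshold is out of reach", {
  p <- sensory_params(in_thres = 2, xi_range = 0.3)
  st <- asel_state()
  set.seed(1)
  for (k in 1:500) st <- step_asel(st, 1, 0.5, p, dt = 0.01)
  expect_identical(st$V, 0)
})

test_that("channel-state occupancy u + h is conserved", {
  st <- aser_state()
  set.seed(2)
  for (k in 1:1000) st <- step_aser(st, runif(1, -1, 0), 0, 0, dt = 0.01)
  expect_lt(abs(st$u + st$h - 1), 1e-9)
  stL <- asel_state()
  for (k in 1:1000) stL <- step_asel(stL, runif(1), 0, dt = 0.01)
  expect_lt(abs(stL$u + stL$h - 1), 1e-9)
})

test_that("ASER peak grows with the down-step and saturates (concave)", {
  steps <- c(-0.25, -0.5, -0.75, -1.0)
  peaks <- vapply(steps, function(s) max(run_aser_trace(s)), numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(diff(peaks)) < 0))
  # the high-accuracy reference integrator agrees on shape and values
  ref <- vapply(steps, aser_oracle_peak, numeric(1))
  expect_true(all(diff(ref) > 0))
  expect_true(all(diff(diff(ref)) < 0))
  expect_equal(peaks, ref, tolerance = 0.02)
})

test_that("evoked traces rise fast, decay slowly, with a single maximum", {
  for (trace in list(run_aser_trace(-0.5), {
    p <- sensory_params(xi_range = 0)
    st <- asel_state()
    n <- 4000
    V <- numeric(n + 1)
    set.seed(1)
    for (i in seq_len(n)) {
      st <- step_asel(st, if (i == 1) 1 else 0, 0, p, dt = 0.01)
      V[i + 1] <- st$V
    }
    V
  })) {
    pk <- which.max(trace)
    expect_gt(max(trace), 0)
    # single local maximum: strictly up before the peak plateau, down after
    d <- diff(trace)
    sign_changes <- sum(abs(diff(sign(d[d != 0]))) > 0)
    expect_lte(sign_changes, 1)
    t_rise <- pk
    after <- trace[pk:length(trace)]
    t_decay <- which(after < 0.1 * trace[pk])[1]
    expect_false(is.na(t_decay))
    expect_lt(t_rise, t_decay)
  }
})

test_that("ASEL depolarization is all-or-none with step-size-dependent probability", {
  steps <- c(0.25, 0.5, 0.75, 1.0)
  prot <- run_step_protocol("ASEL", steps, n_reps = 200, duration = 15,
                            seed = 11)
  act <- prot$peaks |>
    dplyr::group_by(step) |>
    dplyr::summarise(freq = mean(activated), .groups = "drop")
  expect_true(all(diff(act$freq) >= 0))
  n_act <- round(act$freq * 200)
  trend <- stats::prop.trend.test(n_act, rep(200, 4))
  expect_lt(trend$p.value / 2, 0.01) # one-sided, increasing
  pk <- prot$peaks$peak[prot$peaks$activated]
  expect_lt(sd(pk) / mean(pk), 0.05)
  # ASEL voltage stays below its calcium reversal potential
  expect_true(all(prot$traces$V <= sensory_params()$E_L_Ca + 1e-12))
})

test_that("ASER ignores up-steps in the protocol driver", {
  prot <- run_step_protocol("ASER", c(-0.5), n_reps = 1, seed = 1)
  expect_gt(max(prot$traces$V), 0)
  st <- aser_state()
  for (i in 1:500) st <- step_aser(st, if (i == 1) 0.5 else 0, 0, 0, dt = 0.01)
  expect_identical(st$V, 0)
})

test_that("sensory steppers reject invalid inputs", {
  expect_error(step_aser(aser_state(), 1.5), "delta_c")
  expect_error(step_aser(list(V = NaN, u = 1, h = 0, alpha = 0, g = 0), 0),
               "non-finite")
  expect_error(step_asel(asel_state(), 0.5, net_L = 1.2), "net_L")
})

test_that("asel_afferent is tanh-bounded and zero at rest", {
  con <- load_connectome()
  # with all reversal potentials at rest (0) the resting network is silent
  m <- model_from_params(con, w_c = 1, E = 0, w_g = 0.5, b = 0)
  v0 <- setNames(numeric(30), con$neurons)
  expect_equal(asel_afferent(v0, m), 0)
  v <- setNames(rep(2, 30), con$neurons)
  v["ASEL"] <- 0
  expect_lt(abs(asel_afferent(v, m)), 1)
  # large-weight limit saturates toward +/- 1
  m2 <- model_from_params(con, w_c = 2, E = 2, w_g = 0, b = 5)
  expect_gt(asel_afferent(v0, m2), 0.99)
})

test_that("plain-R sensory steppers match the compiled simulator exactly", {
  con <- load_connectome()
  # zero weights isolate the sensory neurons inside the full simulation
  m <- model_from_params(con, w_c = 0, E = 0, w_g = 0, b = 0,
                         E_R_ext = 1.3, E_L_Ca = 0.8)
  dt <- 0.01
  tr <- simulate_run(m, environment_isotropic(), duration = 20, dt = dt,
                     seed = 3, start = list(x = 0, y = 0, theta = 0),
                     stimulus = list(time = 5, delta_c = -0.6))
  p <- sensory_params(E_R_ext = 1.3, E_L_Ca = 0.8)
  st <- aser_state()
  V <- numeric(nrow(tr))
  stim_i <- round(5 / dt) + 1L
  for (i in seq_len(nrow(tr) - 1)) {
    st <- step_aser(st, if (i == stim_i) -0.6 else 0, 0, 0, p, dt)
    V[i + 1] <- st$V
  }
  expect_equal(tr$V_ASER, V, tolerance = 1e-12)

  # and the ASEL route, with the trigger noise disabled for determinism
  sp <- sensory_params(E_R_ext = 1.3, E_L_Ca = 0.8, xi_range = 0)
  m2 <- model_from_params(con, w_c = 0, E = 0, w_g = 0, b = 0,
                          E_R_ext = 1.3, E_L_Ca = 0.8, sensory = sp)
  tr2 <- simulate_run(m2, environment_isotropic(), duration = 20, dt = dt,
                      seed = 3, start = list(x = 0, y = 0, theta = 0),
                      stimulus = list(time = 5, delta_c = 0.9))
  stL <- asel_state()
  VL <- numeric(nrow(tr2))
  for (i in seq_len(nrow(tr2) - 1)) {
    stL <- step_asel(stL, if (i == stim_i) 0.9 else 0, 0, sp, dt)
    VL[i + 1] <- stL$V
  }
  expect_equal(tr2$V_ASEL, VL, tolerance = 1e-12)
})

test_that("peak voltage converges as dt is refined", {
  p1 <- max(run_aser_trace(-0.5, dt = 0.01))
  p2 <- max(run_aser_trace(-0.5, dt = 0.005))
  expect_lt(abs(p2 - p1) / p1, 0.01)
})
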