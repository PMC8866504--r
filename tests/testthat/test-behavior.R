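test_that("cycle series: straight motion toward the peak has zero bias and bearing", {
  env <- environment_conical(peak = c(0, 0))
  dtr <- 0.05
  tt <- seq(0, 42, by = dtr)
  # moving in -x direction from (4, 0): straight toward the peak
  x <- 4 - 0.022 * tt
  traj <- synthetic_trajectory(t = tt, x = x, y = rep(0, length(tt)),
                               theta = rep(pi, length(tt)),
                               phi = rep(0, length(tt)), env = env)
  cs <- cycle_series(traj)
  expect_true(all(cs$turning_bias == 0))
  expect_true(all(cs$turning_rate == 0))
  expect_true(all(abs(cs$bearing) < 1e-6))
  # translational gradient positive (moving up-gradient), normal ~ 0
  expect_true(all(cs$trans_grad > 0))
  expect_true(all(abs(cs$normal_grad) < 1e-9))
})

test_that("cycle series: constant turning rate integrates to its bias", {
  env <- environment_isotropic()
  dtr <- 0.05
  tt <- seq(0, 42, by = dtr)
  phi0 <- 0.1 # rad/s
  theta <- phi0 * tt
  x <- cumsum(c(0, 0.022 * cos(theta[-length(tt)]) * dtr))
  y <- cumsum(c(0, 0.022 * sin(theta[-length(tt)]) * dtr))
  traj <- synthetic_trajectory(t = tt, x = x, y = y, theta = theta,
                               phi = rep(phi0, length(tt)), env = env)
  cs <- cycle_series(traj)
  expect_equal(cs$turning_bias,
               rep(phi0 * 4.2 * 180 / pi, nrow(cs)), tolerance = 1e-6)
  expect_true(all(is.na(cs$bearing))) # no peak in an isotropic world
  expect_error(cycle_series(traj[1:20, ], env), "2 locomotion cycles")
})

test_that("relationship curves recover a known antisymmetric generator", {
  set.seed(5)
  n <- 4000
  bearing <- runif(n, -180, 180)
  bias <- -20 * sin(bearing * pi / 180) + rnorm(n, 0, 2)
  series <- tibble::tibble(
    turning_bias = bias, bearing = bearing,
    normal_grad_norm = runif(n, -1, 1), trans_grad_norm = runif(n, -1, 1))
  curves <- relationship_curves(series)
  bb <- curves[curves$panel == "bearing", ]
  expect_equal(nrow(bb), 13)
  expect_lt(max(abs(bb$mean_bias - -20 * sin(bb$bin_mid * pi / 180))), 1)
  # sign-split means bracket the signed mean where both signs occur
  occ_p <- !is.na(bb$mean_pos) & bb$n > 5
  occ_n <- !is.na(bb$mean_neg) & bb$n > 5
  expect_true(all(bb$mean_pos[occ_p] >= bb$mean_bias[occ_p]))
  expect_true(all(bb$mean_neg[occ_n] <= bb$mean_bias[occ_n]))
  # a zero-bias series gives all-zero means
  z <- series
  z$turning_bias <- 0
  zc <- relationship_curves(z)
  expect_true(all(zc$mean_bias[zc$n > 0] == 0))
})

test_that("empty bins are reported as missing, not zero", {
  series <- tibble::tibble(turning_bias = c(5, -5), bearing = c(10, 12),
                           normal_grad_norm = c(0.1, 0.1),
                           trans_grad_norm = c(0.1, 0.1))
  curves <- relationship_curves(series)
  bb <- curves[curves$panel == "bearing", ]
  expect_true(any(bb$n == 0))
  expect_true(all(is.na(bb$mean_bias[bb$n == 0])))
})

test_that("random-walk statistics match an i.i.d. normal synthesizer", {
  set.seed(11)
  tracks <- lapply(1:150, function(i) {
    tt <- seq(2.1, by = 4.2, length.out = 120)
    tibble::tibble(t = tt, turning_rate = rnorm(120, 0, 32.3))
  })
  rw <- random_walk_stats(tracks)
  gl <- glance(rw)
  # K-S P values are uniform under the null: mean near 0.5
  expect_gt(gl$mean_ks_p, 0.4)
  expect_lt(gl$mean_ks_p, 0.6)
  expect_lt(abs(gl$mean_mu), 2)
  expect_lt(abs(gl$mean_sigma - 32.3), 2)
  # i.i.d. rates carry no lag correlation
  expect_lt(abs(gl$lag_corr_6s), 0.05)
  expect_lt(abs(gl$lag_corr_12s), 0.05)
  expect_error(random_walk_stats(list()), "no tracks")
})

test_that("liquid-style interpolated rates decorrelate across one interval", {
  # per-cycle rates sampled from the piecewise-linear guidepost process
  tracks <- lapply(1:40, function(i) {
    sch <- liquid_schedule(0, 1, duration = 600, seed = i)
    tt <- seq(0, 560, by = 4.2)
    tibble::tibble(t = tt,
                   turning_rate = vapply(tt, function(t) 32.3 * strength_at(sch, t),
                                         numeric(1)))
  })
  rw <- random_walk_stats(tracks)
  gl <- glance(rw)
  expect_gt(gl$lag_corr_6s, gl$lag_corr_12s + 0.2)
  # the decay table heads toward zero within the strip
  dec <- rw$decay
  early <- dec$mean_rate[dec$second == 0]
  late <- dec$mean_rate[dec$second == 20]
  expect_gt(mean(abs(early)), mean(abs(late)))
})

test_that("steering response at zero step equals the unstimulated bias", {
  con <- load_connectome()
  m <- decode_genome(random_genome(con, 2), con)
  r <- steering_response(m, phase = pi / 2, step = 0, dt = 0.01, seed = 4,
                         settle_cycles = 5)
  expect_equal(r$response, r$baseline)
  expect_equal(r$n, 1L)
})

test_that("opposed sensory polarities give opposite-signed steering responses", {
  con <- load_connectome()
  # engineered pathway: ASER excites and ASEL inhibits AIYL -> AIZL -> SMBDL,
  # breaking the dorsoventral symmetry so a step visibly steers the agent
  m <- model_from_params(con, w_c = 0, E = 1, w_g = 0, b = -1,
                         w_osc = 1, w_nmj = 0.5)
  path <- c(which(con$chem$pre == "ASER" & con$chem$post == "AIYL"),
            which(con$chem$pre == "AIYL" & con$chem$post == "AIZL"),
            which(con$chem$pre == "AIZL" & con$chem$post == "SMBDL"))
  m$w_c[path] <- 2
  asel_e <- which(con$chem$pre == "ASEL" & con$chem$post == "AIYL")
  m$w_c[asel_e] <- 2
  m$E[asel_e] <- -2
  m <- set_param(m, "b", c(SMBDL = -2, SMBDR = -2, SMBVL = -2, SMBVR = -2))

  rd <- steering_response(m, phase = 0.75 * pi, step = -0.8, dt = 0.01,
                          seed = 4, settle_cycles = 5)
  rd2 <- steering_response(m, phase = 0.75 * pi, step = -0.8, dt = 0.01,
                           seed = 9, settle_cycles = 5)
  expect_equal(rd$response, rd2$response) # deterministic: no noise consumed
  expect_equal(rd$n, 1L)
  ru <- steering_response(m, phase = 0.75 * pi, step = 0.8, n_reps = 20,
                          dt = 0.01, seed = 4, settle_cycles = 5)
  d_down <- rd$response - rd$baseline
  d_up <- ru$response - ru$baseline
  expect_gt(d_down, 0.01)   # excitatory ASER pathway steers dorsally
  expect_lt(d_up, -0.01)    # inhibitory ASEL pathway steers the other way
})

test_that("sharp-turn overlay: identity, forced reversal, and gradient bias", {
  env <- environment_conical(peak = c(0, 0))
  tt <- seq(0, 84, by = 0.05)
  x <- 4 - 0.022 * tt
  traj <- synthetic_trajectory(t = tt, x = x, y = rep(0, length(tt)),
                               theta = rep(pi, length(tt)), env = env)
  # probability zero: exact identity
  same <- sharp_turn_overlay(traj, function(g) 0, function(n) rep(pi, n))
  expect_identical(same$x, traj$x)
  expect_identical(same$theta, traj$theta)
  # missing probability function: warn and disable
  expect_warning(off <- sharp_turn_overlay(traj, NULL, function(n) pi),
                 "disabled")
  expect_identical(off$x, traj$x)
  # probability one with angle pi: heading flips every cycle
  rev <- sharp_turn_overlay(traj, function(g) 1, function(n) rep(pi, n),
                            seed = 2)
  ev <- attr(rev, "events")
  expect_gt(nrow(ev), 10)
  spc <- round(4.2 / 0.05)
  expect_equal(rev$theta[spc + 2] - traj$theta[spc + 2], pi)
  expect_equal(rev$theta[2 * spc + 2] - traj$theta[2 * spc + 2], 2 * pi)

  # a probability decreasing in the gradient produces more turns on
  # down-gradient runs than on up-gradient runs
  prob <- function(g) stats::plogis(-300 * g)
  n_events <- function(tr, seed) {
    nrow(attr(sharp_turn_overlay(tr, prob, function(n) runif(n, -pi, pi),
                                 seed = seed), "events"))
  }
  up <- traj # moving up-gradient (toward the peak)
  down <- synthetic_trajectory(t = tt, x = 1 + 0.022 * tt,
                               y = rep(0, length(tt)),
                               theta = rep(0, length(tt)), env = env)
  ups <- sum(vapply(1:30, function(s) n_events(up, s), numeric(1)))
  downs <- sum(vapply(1:30, function(s) n_events(down, s), numeric(1)))
  expect_gt(downs, ups)
})

test_that("ablation battery reproduces the unablated CI for an empty set", {
  con <- load_connectome()
  m <- decode_genome(random_genome(con, 6), con)
  env <- environment_conical()
  bat <- ablation_battery(list(m), list(none = character(0), ASE = c("ASEL", "ASER")),
                          env, runs_per_model = 2, duration = 60, seed = 3)
  expect_equal(nrow(bat), 2)
  summ <- attr(bat, "summary")
  expect_setequal(summ$ablation, c("none", "ASE"))
  # the unablated cell equals direct simulation with the same seeds
  withr_seed_val <- bat$mean_ci[bat$ablation == "none"]
  expect_true(is.finite(withr_seed_val))
  expect_error(
    ablation_battery(list(m), list(bad = "XYZ"), env, runs_per_model = 1,
                     duration = 20),
    "unknown neuron")
})
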