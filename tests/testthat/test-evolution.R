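test_that("chemotaxis index matches its analytic cases", {
  env <- environment_conical()
  tt <- seq(0, 100, by = 0.1)
  # stationary: r(t) = r(0)
  stat <- tibble::tibble(t = tt, x = 3, y = 0)
  expect_equal(chemotaxis_index(stat, peak = c(0, 0)), 0)
  # sitting on the peak from the first instant after start
  onpeak <- tibble::tibble(t = tt, x = c(1, rep(0, length(tt) - 1)), y = 0)
  expect_equal(chemotaxis_index(onpeak, peak = c(0, 0)), 1, tolerance = 1e-3)
  # linear approach reaching the peak at T: CI = 0.5 (trapezoid is exact)
  lin <- tibble::tibble(t = tt, x = 3 * (1 - tt / 100), y = 0)
  expect_equal(chemotaxis_index(lin, peak = c(0, 0)), 0.5)
  # starting on the peak is rejected
  expect_error(chemotaxis_index(tibble::tibble(t = tt, x = 0, y = 0),
                                peak = c(0, 0)), "r\\(0\\)")
})

test_that("chemotaxis index quadrature converges under sampling refinement", {
  r_fun <- function(t) 3 * exp(-t / 40)
  ci_at <- function(by) {
    tt <- seq(0, 100, by = by)
    chemotaxis_index(tibble::tibble(t = tt, x = r_fun(tt), y = 0),
                     peak = c(0, 0))
  }
  expect_lt(abs(ci_at(0.1) - ci_at(0.05)), 1e-3)
})

test_that("crossover spawns interior candidates and keeps the best", {
  a <- rep(0.2, 10)
  b <- rep(0.8, 10)
  # identical parents: all candidates coincide with them
  same <- crossover(a, a, function(g) sum(g))
  expect_equal(same$genome, a)
  # candidates are strict convex combinations
  res <- crossover(a, b, function(g) -sum((g - 0.3)^2))
  expect_true(all(res$genome >= 0.2 & res$genome <= 0.8))
  # the candidate closest to 0.3 wins: fraction 1/6 of the way from a to b
  expect_equal(res$genome, (1 - 1 / 6) * a + (1 / 6) * b)
  expect_equal(res$candidate, 1)
  # returned fitness is the max over candidates
  fits <- vapply(1:5, function(k) {
    g <- (1 - k / 6) * a + (k / 6) * b
    -sum((g - 0.3)^2)
  }, numeric(1))
  expect_equal(res$fitness, max(fits))
})

test_that("mutation contracts: identity limits and clipping", {
  g <- runif(50)
  expect_identical(mutate(g, rate = 0), g)
  expect_identical(mutate(g, rate = 1, sd = 0), g)
  set.seed(1)
  m <- mutate(c(0.001, 0.999, rep(0.5, 48)), rate = 1, sd = 0.5)
  expect_true(all(m >= 0 & m <= 1))
  expect_false(identical(m, c(0.001, 0.999, rep(0.5, 48))))
})

test_that("the GA is deterministic and its best fitness is monotone", {
  cfg <- ga_config(pop_size = 12, max_generations = 15,
                   events_per_generation = 6, stagnation_window = 10,
                   stagnation_tol = 1e-9)
  ga1 <- run_ga(cfg, seed = 3, fitness_fn = surrogate_fitness,
                genome_length = 20)
  ga2 <- run_ga(cfg, seed = 3, fitness_fn = surrogate_fitness,
                genome_length = 20)
  expect_identical(ga1$logbook, ga2$logbook)
  expect_identical(ga1$population, ga2$population)
  expect_true(all(diff(ga1$logbook$best) >= 0))
  expect_gt(ga1$best_fitness, 0.9) # surrogate optimum is 1 at genome = 0.7
  # a different seed takes a different path
  ga3 <- run_ga(cfg, seed = 4, fitness_fn = surrogate_fitness,
                genome_length = 20)
  expect_false(identical(ga1$logbook, ga3$logbook))
})

test_that("the GA stops on stagnation and honours a zero generation budget", {
  flat <- function(genome, seed) 0.5
  cfg <- ga_config(pop_size = 6, max_generations = 100,
                   events_per_generation = 2, stagnation_window = 5)
  ga <- run_ga(cfg, seed = 1, fitness_fn = flat, genome_length = 4)
  expect_lte(ga$generations, 7)

  cfg0 <- ga_config(pop_size = 6, max_generations = 0)
  ga0 <- run_ga(cfg0, seed = 1, fitness_fn = flat, genome_length = 4)
  expect_equal(ga0$generations, 0)
  expect_length(ga0$fitness, 6)
})

test_that("tidy and glance summarise a GA fit", {
  cfg <- ga_config(pop_size = 6, max_generations = 4,
                   events_per_generation = 2, stagnation_window = 3,
                   stagnation_tol = 1e-9)
  ga <- run_ga(cfg, seed = 2, fitness_fn = surrogate_fitness,
               genome_length = 8)
  lb <- tidy(ga)
  expect_true(all(c("generation", "best", "mean", "n_evals") %in% names(lb)))
  gl <- glance(ga)
  expect_equal(gl$pop_size, 6)
  expect_equal(gl$best_fitness, max(ga$fitness))
})

test_that("an unguided genome scores near-zero fitness with zero reliability", {
  con <- load_connectome()
  # all-zero weights and neuromuscular gain: straight-line motion
  m <- model_from_params(con)
  g <- m$genome
  cfg <- ga_config(pop_size = 2, fitness_runs = 5, run_duration = 200)
  rec <- evaluate_fitness(g, con, environment_conical(), cfg, seed = 8)
  expect_lt(abs(rec$fitness), 0.2)
  expect_equal(rec$reliability, 0)
  # determinism contract
  rec2 <- evaluate_fitness(g, con, environment_conical(), cfg, seed = 8)
  expect_equal(rec$fitness, rec2$fitness)
  expect_identical(rec$cis, rec2$cis)
})

test_that("simulation runs are reproducible and divergence is flagged", {
  con <- load_connectome()
  m <- decode_genome(random_genome(con, 31), con)
  env <- environment_conical()
  t1 <- simulate_run(m, env, duration = 50, seed = 17)
  t2 <- simulate_run(m, env, duration = 50, seed = 17)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$V_ASEL, t2$V_ASEL)

  # maximal excitation everywhere overloads the explicitly integrated
  # sensory membrane (the network neurons are unconditionally stable)
  g_bad <- rep(1, n_free_parameters(con))
  m_bad <- decode_genome(g_bad, con)
  expect_warning(
    tr <- simulate_run(m_bad, env, duration = 20, seed = 1),
    "diverged"
  )
  expect_true(attr(tr, "diverged"))
  # and evaluate_fitness scores such a run as zero
  cfg <- ga_config(pop_size = 2, fitness_runs = 2, run_duration = 20)
  rec <- evaluate_fitness(g_bad, con, env, cfg, seed = 1)
  expect_equal(rec$fitness, 0)
  expect_equal(rec$diverged, 2)
})
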