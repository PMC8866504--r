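#' Chemotaxis index of a trajectory
#'
#' `CI = 1 - (1/T) * integral of r(t)/r(0) dt`, where `r(t)` is the distance
#' to the NaCl peak. A stationary agent scores 0, an agent sitting on the
#' peak the whole time scores 1, and a linear approach that reaches the peak
#' exactly at `T` scores 0.5. Computed by trapezoidal quadrature over the
#' trajectory samples.
#'
#' @param traj Tibble with `t`, `x`, `y` (e.g. a `worm_trajectory`).
#' @param peak Peak position `c(x, y)`; defaults to the trajectory
#'   environment's peak.
#' @param total_time `T`; defaults to the trajectory's final time.
#' @return Scalar CI (at most 1).
#' @export
chemotaxis_index <- function(traj, peak = NULL, total_time = NULL) {
  peak <- peak %||% attr(traj, "env")$peak
  stopifnot(length(peak) == 2)
  total_time <- total_time %||% max(traj$t)
  r <- sqrt((traj$x - peak[1])^2 + (traj$y - peak[2])^2)
  if (r[1] == 0) abort("trajectory starts on the peak: r(0) = 0")
  keep <- traj$t <= total_time
  tt <- traj$t[keep]
  rr <- r[keep] / r[1]
  integral <- sum(diff(tt) * (rr[-1] + rr[-length(rr)]) / 2)
  1 - integral / total_time
}

#' Genetic-algorithm settings
#'
#' Defaults follow the evolutionary protocol used to evolve the klinotaxis
#' models: population 300, crossover rate 0.8 with five children spawned
#' evenly along the parents' connecting line (only the best kept), mutation
#' rate 0.3 with whole-vector Gaussian noise of SD 0.05, stopping after 1000
#' generations or 50 generations without meaningful improvement of the best
#' fitness. One generation performs `events_per_generation` steady-state
#' mating events (default half the population size).
#'
#' @param pop_size Population size.
#' @param crossover_rate Probability a mating event performs crossover.
#' @param mutation_rate Probability the child is mutated.
#' @param mutation_sd SD of the Gaussian mutation noise.
#' @param n_children_per_cross Candidates spawned per crossover.
#' @param max_generations Generation cap.
#' @param stagnation_window,stagnation_tol Stop when the best fitness improves
#'   by less than `stagnation_tol` over this many consecutive generations.
#' @param events_per_generation Mating events per generation
#'   (`NULL` = `pop_size %/% 2`).
#' @param fitness_runs Simulated trials averaged per fitness evaluation.
#' @param run_duration Trial length (s).
#' @param start_radius Initial distance from the peak (cm).
#' @param dt Integration step (s).
#' @param per_gene_mutation Mutate slots independently with probability
#'   `mutation_rate` instead of the whole vector at once.
#' @param common_eval_seeds Use one fixed evaluation seed for every fitness
#'   call within a GA run (common random numbers). With few stochastic trials
#'   per evaluation this makes fitness differences between genomes reflect
#'   the genomes rather than trial luck; the alternative (a fresh seed per
#'   evaluation) re-randomizes initial headings every time.
#' @param heading_mode `"even"` (default) starts the fitness trials at
#'   evenly spaced initial headings, so the mean CI of any open-loop
#'   (non-sensing) strategy averages out over orientations and only genuine
#'   gradient steering scores above the circling baseline; `"random"` draws
#'   each trial's heading uniformly, which at small `fitness_runs` lets the
#'   search exploit heading luck.
#' @return Named list of settings.
#' @export
ga_config <- function(pop_size = 300, crossover_rate = 0.8,
                      mutation_rate = 0.3, mutation_sd = 0.05,
                      n_children_per_cross = 5, max_generations = 1000,
                      stagnation_window = 50, stagnation_tol = 1e-3,
                      events_per_generation = NULL, fitness_runs = 5,
                      run_duration = 800, start_radius = 4.5, dt = 0.01,
                      per_gene_mutation = FALSE, common_eval_seeds = FALSE,
                      heading_mode = c("even", "random")) {
  stopifnot(pop_size >= 2, crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, mutation_sd >= 0,
            n_children_per_cross >= 1, max_generations >= 0,
            run_duration > 0, dt > 0, fitness_runs >= 1)
  list(pop_size = pop_size, crossover_rate = crossover_rate,
       mutation_rate = mutation_rate, mutation_sd = mutation_sd,
       n_children_per_cross = n_children_per_cross,
       max_generations = max_generations,
       stagnation_window = stagnation_window,
       stagnation_tol = stagnation_tol,
       events_per_generation = events_per_generation %||% (pop_size %/% 2),
       fitness_runs = fitness_runs, run_duration = run_duration,
       start_radius = start_radius, dt = dt,
       per_gene_mutation = per_gene_mutation,
       common_eval_seeds = common_eval_seeds,
       heading_mode = match.arg(heading_mode))
}

#' Evaluate the chemotaxis fitness of a genome
#'
#' Decodes the genome, simulates `fitness_runs` independent trials with
#' random initial headings, and returns the mean chemotaxis index together
#' with the reliability (fraction of trials that entered the 0.1 cm capture
#' radius around the peak). A diverged trial scores CI = 0.
#'
#' @param genome Genome vector in \[0, 1\].
#' @param connectome A `connectome`.
#' @param env An `env_spec`.
#' @param config From [ga_config()].
#' @param seed Integer seed (fixes the trial seeds).
#' @param ranges,tau,sensory Passed to [decode_genome()].
#' @return One-row tibble: `fitness` (mean CI), `reliability`, `n_runs`,
#'   `diverged` count, and list-columns `cis`, `seeds`.
#' @export
evaluate_fitness <- function(genome, connectome, env, config = ga_config(),
                             seed = 1, ranges = decode_ranges(), tau = 0.1,
                             sensory = sensory_params()) {
  model <- decode_genome(genome, connectome, ranges, tau, sensory)
  withr_seed(seed, {
    run_seeds <- sample.int(.Machine$integer.max, config$fitness_runs)
  })
  even <- identical(config$heading_mode %||% "even", "even")
  cis <- numeric(config$fitness_runs)
  caught <- logical(config$fitness_runs)
  div <- 0L
  for (r in seq_len(config$fitness_runs)) {
    start <- if (even) {
      th <- 2 * pi * (r - 1) / config$fitness_runs
      list(x = env$peak[1] + config$start_radius, y = env$peak[2], theta = th)
    } # else NULL: uniform-random heading from the run seed
    traj <- suppressWarnings(
      simulate_run(model, env, duration = config$run_duration,
                   dt = config$dt, seed = run_seeds[r], start = start,
                   start_radius = config$start_radius, record_every = 0))
    if (attr(traj, "diverged") || is.na(attr(traj, "ci"))) {
      cis[r] <- 0
      div <- div + 1L
    } else {
      cis[r] <- attr(traj, "ci")
      caught[r] <- attr(traj, "captured")
    }
  }
  tibble(fitness = mean(cis), reliability = mean(caught),
         n_runs = config$fitness_runs, diverged = div,
         cis = list(cis), seeds = list(run_seeds))
}

#' Crossover: pick the best point on the parents' connecting line
#'
#' Spawns `n_children` candidates evenly along the open segment between the
#' parents (fractions `k / (n_children + 1)`, excluding the endpoints, which
#' are the parents themselves), evaluates each with `fitness_fn`, and returns
#' the highest scoring one.
#'
#' @param parent_a,parent_b Genome vectors of equal length.
#' @param fitness_fn Function `genome -> numeric` fitness.
#' @param n_children Number of candidates.
#' @return List with `genome`, `fitness`, and `candidate` (index chosen).
#' @export
crossover <- function(parent_a, parent_b, fitness_fn, n_children = 5) {
  stopifnot(length(parent_a) == length(parent_b))
  fracs <- seq_len(n_children) / (n_children + 1)
  cands <- lapply(fracs, function(f) (1 - f) * parent_a + f * parent_b)
  fits <- vapply(cands, fitness_fn, numeric(1))
  best <- which.max(fits)
  list(genome = cands[[best]], fitness = fits[best], candidate = best)
}

#' Gaussian mutation with clipping
#'
#' With probability `rate` the child receives i.i.d. `N(0, sd^2)` noise on
#' every slot (whole-vector reading); with `per_gene = TRUE` each slot is
#' instead perturbed independently with probability `rate`. Values are
#' clipped back to \[0, 1\]. Uses the current RNG state.
#'
#' @param child Genome vector.
#' @param rate Mutation probability.
#' @param sd Noise SD.
#' @param per_gene Per-slot Bernoulli variant.
#' @return Mutated genome in \[0, 1\].
#' @export
mutate <- function(child, rate = 0.3, sd = 0.05, per_gene = FALSE) {
  if (rate <= 0 || sd <= 0) return(child)
  if (per_gene) {
    hit <- runif(length(child)) < rate
    child[hit] <- child[hit] + rnorm(sum(hit), 0, sd)
  } else if (runif(1) < rate) {
    child <- child + rnorm(length(child), 0, sd)
  }
  pmin(pmax(child, 0), 1)
}

#' Evolve a population of worm models
#'
#' Steady-state genetic algorithm over real-valued genomes in \[0, 1\]. Each
#' mating event selects two random parents (uniform with replacement across
#' the population, resampled if identical indices), performs line crossover
#' with probability `crossover_rate`, optionally mutates the child, and
#' replaces the lower-scoring parent if the child beats it -- so the best
#' fitness in the population is non-decreasing. Iteration stops at
#' `max_generations` or when the best fitness has not improved by
#' `stagnation_tol` within `stagnation_window` generations.
#'
#' @param config From [ga_config()].
#' @param seed Integer master seed; fixes the whole evolution.
#' @param fitness_fn Optional `function(genome, seed) -> numeric` (or a list
#'   with elements `fitness` and `reliability`). When `NULL`, the chemotaxis
#'   fitness [evaluate_fitness()] on `connectome` + `env` is used.
#' @param connectome,env Required when `fitness_fn` is `NULL`.
#' @param genome_length Slot count; defaults to [n_free_parameters()] of the
#'   connectome.
#' @param init_population Optional matrix (one genome per row) to warm-start
#'   from, e.g. the `population` of a previous fit; rows are recycled or
#'   subsampled to `pop_size`. All fitness values are re-evaluated.
#' @param ranges,tau,sensory Passed through to the chemotaxis fitness.
#' @param verbose Print per-generation progress.
#' @return A `klinotaxis_ga` object: `population` (matrix, one genome per
#'   row), `fitness`, `reliability`, `logbook` tibble, `best_genome`,
#'   `config`, `seed`, `n_evals`.
#' @export
run_ga <- function(config = ga_config(), seed = 1, fitness_fn = NULL,
                   connectome = NULL, env = NULL, genome_length = NULL,
                   init_population = NULL, ranges = decode_ranges(),
                   tau = 0.1, sensory = sensory_params(), verbose = FALSE) {
  if (is.null(fitness_fn)) {
    if (is.null(connectome) || is.null(env)) {
      abort("supply either fitness_fn or both connectome and env")
    }
    fitness_fn <- function(genome, seed) {
      rec <- evaluate_fitness(genome, connectome, env, config, seed,
                              ranges, tau, sensory)
      list(fitness = rec$fitness, reliability = rec$reliability)
    }
  }
  genome_length <- genome_length %||% n_free_parameters(connectome)
  n_evals <- 0L
  eval1 <- function(genome, s) {
    n_evals <<- n_evals + 1L
    out <- fitness_fn(genome, s)
    if (is.list(out)) c(out$fitness, out$reliability %||% NA_real_)
    else c(out, NA_real_)
  }

  withr_seed(seed, {
    P <- config$pop_size
    pop <- if (is.null(init_population)) {
      matrix(runif(P * genome_length), nrow = P)
    } else {
      stopifnot(ncol(init_population) == genome_length)
      init_population[rep_len(seq_len(nrow(init_population)), P), ,
                      drop = FALSE]
    }
    eval_seeds <- if (isTRUE(config$common_eval_seeds)) {
      fixed <- sample.int(.Machine$integer.max, 1)
      function(k) rep_len(fixed, k)
    } else {
      function(k) sample.int(.Machine$integer.max, k)
    }
    fr <- t(vapply(seq_len(P),
                   function(i) eval1(pop[i, ], eval_seeds(1)), numeric(2)))
    fitness <- fr[, 1]
    reliability <- fr[, 2]

    logbook <- list()
    best_hist <- max(fitness)
    gen <- 0L
    while (gen < config$max_generations) {
      gen <- gen + 1L
      for (ev in seq_len(config$events_per_generation)) {
        if (runif(1) >= config$crossover_rate) next
        pr <- sample.int(P, 1)
        repeat {
          pr2 <- sample.int(P, 1)
          if (pr2 != pr) break
        }
        fracs <- seq_len(config$n_children_per_cross) /
          (config$n_children_per_cross + 1)
        cand_fit <- -Inf
        child <- NULL
        child_rel <- NA_real_
        for (f in fracs) {
          g <- (1 - f) * pop[pr, ] + f * pop[pr2, ]
          res <- eval1(g, eval_seeds(1))
          if (res[1] > cand_fit) {
            cand_fit <- res[1]
            child <- g
            child_rel <- res[2]
          }
        }
        mutated <- mutate(child, config$mutation_rate, config$mutation_sd,
                          config$per_gene_mutation)
        if (!identical(mutated, child)) {
          child <- mutated
          res <- eval1(child, eval_seeds(1))
          cand_fit <- res[1]
          child_rel <- res[2]
        }
        lower <- if (fitness[pr] <= fitness[pr2]) pr else pr2
        if (cand_fit > fitness[lower]) {
          pop[lower, ] <- child
          fitness[lower] <- cand_fit
          reliability[lower] <- child_rel
        }
      }
      best_hist <- c(best_hist, max(fitness))
      logbook[[gen]] <- tibble(generation = gen, best = max(fitness),
                               mean = mean(fitness), n_evals = n_evals)
      if (verbose) {
        message(sprintf("gen %d: best %.4f mean %.4f (%d evals)",
                        gen, max(fitness), mean(fitness), n_evals))
      }
      w <- config$stagnation_window
      if (gen > w &&
          best_hist[length(best_hist)] - best_hist[length(best_hist) - w] <
            config$stagnation_tol) {
        break
      }
    }
  })
  logbook <- if (length(logbook)) dplyr::bind_rows(logbook) else
    tibble(generation = integer(), best = numeric(), mean = numeric(),
           n_evals = integer())
  best <- which.max(fitness)
  structure(list(population = pop, fitness = fitness,
                 reliability = reliability, logbook = logbook,
                 best_genome = pop[best, ], best_fitness = fitness[best],
                 best_reliability = reliability[best],
                 config = config, seed = seed, n_evals = n_evals,
                 generations = nrow(logbook)),
            class = "klinotaxis_ga")
}

#' @export
print.klinotaxis_ga <- function(x, ...) {
  cat("<klinotaxis_ga>", nrow(x$population), "individuals,",
      x$generations, "generations,", x$n_evals, "fitness evaluations\n")
  cat(sprintf("  best fitness %.4f (reliability %s)\n", x$best_fitness,
              ifelse(is.na(x$best_reliability), "n/a",
                     sprintf("%.2f", x$best_reliability))))
  invisible(x)
}

#' Successful-model filter
#'
#' Indices of population members with fitness above `fitness_min` and
#' reliability above `reliability_min`, the criterion used to define the
#' successful sub-population.
#'
#' @param ga A `klinotaxis_ga`.
#' @param fitness_min,reliability_min Thresholds (0.7 and 0.5 by default).
#' @return Integer indices.
#' @export
successful_models <- function(ga, fitness_min = 0.7, reliability_min = 0.5) {
  which(ga$fitness > fitness_min &
          !is.na(ga$reliability) & ga$reliability > reliability_min)
}

#' Optimize liquid-synapse SDs against the target random-walk statistics
#'
#' Stage-B optimization: with the stage-A genome fixed, the per-edge SDs of
#' the liquid synapses are tuned so the turning-rate distribution in an
#' isotropic environment matches a reference normal (mean 0, SD 32.3
#' degrees/mm in behaving worms). To keep the search desk-scale the SD vector
#' is parameterized as a single global scale times per-edge multipliers
#' (fixed at 1 unless `per_edge = TRUE`). The similarity score is
#' `-( |mu|/sigma_ref + |sigma - sigma_ref|/sigma_ref ) + mean K-S P value`,
#' maximal when the simulated statistics hit the target exactly.
#'
#' @param model The evolved `worm_model`.
#' @param target_mu,target_sigma Reference normal parameters (degrees/mm).
#' @param config [ga_config()] for the SD search (use a small population).
#' @param n_tracks Isotropic tracks per evaluation.
#' @param track_duration Track length (s).
#' @param sigma_max Upper bound of the global SD scale (weight units).
#' @param per_edge Also evolve per-edge multipliers in \[0.5, 1.5\].
#' @param seed Integer seed.
#' @return A `liquid_fit` object: `sigma` (per-edge SD vector), `scale`,
#'   `stats` (achieved [random_walk_stats()] glance), `ga` (the underlying
#'   fit), `model`.
#' @export
optimize_liquid_sds <- function(model, target_mu = 0, target_sigma = 32.3,
                                config = ga_config(pop_size = 12,
                                                   max_generations = 8,
                                                   events_per_generation = 6,
                                                   stagnation_window = 4),
                                n_tracks = 3, track_duration = 300,
                                sigma_max = 1, per_edge = FALSE, seed = 1) {
  env <- environment_isotropic()
  n_edges <- nrow(model$connectome$chem)
  glen <- if (per_edge) 1L + n_edges else 1L
  decode_sigma <- function(g) {
    scale <- g[1] * sigma_max
    mult <- if (per_edge) 0.5 + g[-1] else rep(1, n_edges)
    scale * mult
  }
  sim_stats <- function(sigma, s) {
    withr_seed(s, run_seeds <- sample.int(.Machine$integer.max, n_tracks))
    tracks <- lapply(run_seeds, function(rs) {
      suppressWarnings(
        simulate_run(model, env, duration = track_duration, dt = config$dt,
                     seed = rs, liquid = sigma,
                     start = list(x = 0, y = 0, theta = 0)))
    })
    ok <- !vapply(tracks, function(tr) attr(tr, "diverged"), logical(1))
    if (!any(ok)) return(NULL)
    random_walk_stats(tracks[ok], target_mu, target_sigma)
  }
  fitness_fn <- function(g, s) {
    st <- sim_stats(decode_sigma(g), s)
    if (is.null(st)) return(-1e6)
    mu <- mean(st$per_track$mu)
    sig <- mean(st$per_track$sigma)
    if (!is.finite(mu) || !is.finite(sig)) return(-1e6)
    -(abs(mu - target_mu) / target_sigma +
        abs(sig - target_sigma) / target_sigma) + mean(st$per_track$ks_p)
  }
  ga <- run_ga(config, seed = seed, fitness_fn = fitness_fn,
               genome_length = glen)
  sigma <- decode_sigma(ga$best_genome)
  final <- sim_stats(sigma, seed + 1)
  structure(list(sigma = sigma, scale = ga$best_genome[1] * sigma_max,
                 stats = final, ga = ga, model = model,
                 target_mu = target_mu, target_sigma = target_sigma),
            class = "liquid_fit")
}

#' @export
print.liquid_fit <- function(x, ...) {
  cat("<liquid_fit> global SD scale", signif(x$scale, 4), "\n")
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}
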