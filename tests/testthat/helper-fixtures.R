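# Fixtures are built in code: a connectome is assembled by writing a small
# edge-list CSV and loading it through the public loader, and models are built
# by inverting the affine decode map so tests exercise decode_genome().

make_connectome <- function(chem = NULL, gap = NULL) {
  rows <- list()
  if (!is.null(chem)) {
    rows[[1]] <- data.frame(pre = chem$pre, post = chem$post, type = "chem")
  }
  if (!is.null(gap)) {
    rows[[2]] <- data.frame(pre = gap$a, post = gap$b, type = "gap")
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(pre = character(), post = character(),
                                    type = character())
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  load_connectome(path)
}

# genome slot values that decode to the requested physical parameters
model_from_params <- function(con, w_c = 0, E = 0, w_g = 0, b = 0,
                              E_L_Ca = 1, E_R_ext = 1, w_osc = 0, w_nmj = 0,
                              ranges = decode_ranges(), tau = 0.1,
                              sensory = sensory_params()) {
  inv <- function(v, r) {
    if (r[2] == r[1]) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  nc <- nrow(con$chem)
  ng <- nrow(con$gap)
  nn <- length(con$neurons)
  g <- c(inv(rep_len(w_c, nc), ranges$w_c),
         inv(rep_len(E, nc), ranges$E),
         inv(rep_len(w_g, ng), ranges$w_g),
         inv(rep_len(b, nn), ranges$b),
         inv(E_L_Ca, ranges$E_L_Ca), inv(E_R_ext, ranges$E_R_ext),
         inv(w_osc, ranges$w_osc), inv(w_nmj, ranges$w_nmj))
  sensory$E_L_Ca <- E_L_Ca # keep standalone sensory params in sync
  sensory$E_R_ext <- E_R_ext
  decode_genome(g, con, ranges, tau, sensory)
}

# named per-neuron override of biases etc. on an existing model
set_param <- function(model, field, values) {
  model[[field]][names(values)] <- unname(values)
  model
}

# deterministic surrogate fitness for GA machinery tests: smooth, cheap,
# maximized at genome == 0.7 everywhere
surrogate_fitness <- function(genome, seed) {
  1 - mean((genome - 0.7)^2)
}

# a synthetic trajectory tibble that looks like a simulate_run() output
synthetic_trajectory <- function(t, x, y, theta = NULL, phi = NULL, env) {
  n <- length(t)
  if (is.null(theta)) theta <- atan2(c(diff(y), 0), c(diff(x), 1))
  if (is.null(phi)) phi <- rep(0, n)
  tr <- tibble::tibble(t = t, x = x, y = y, theta = theta, phi = phi,
                       C = concentration(env, x, y, t), dC = 0,
                       out_SMBDL = 0.5, out_SMBDR = 0.5,
                       out_SMBVL = 0.5, out_SMBVR = 0.5,
                       V_ASEL = 0, V_ASER = 0)
  structure(tr, class = c("worm_trajectory", class(tr)), env = env)
}
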