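#' Decode ranges for genome slots
#'
#' Each genome slot lives in \[0, 1\] and is mapped affinely onto a physical
#' range. Defaults bracket the dynamic regimes seen in evolved models:
#' synaptic strengths in \[0, 5\], reversal potentials in \[-5, 5\], biases in
#' \[-5, 5\] (deep sigmoid saturation requires large negative biases), the
#' oscillator coupling in \[0, 5\], and the neuromuscular gain in \[0, 2\]
#' rad/s per unit output. The width matters: a synaptic stage's small-signal
#' gain is roughly `w f' (E - V*) / (1 + sum w f)`, and with strengths and
#' reversal potentials capped near 2 no multi-stage pathway through the
#' interneuron layers can reach unit gain -- sensory responses then die
#' before the motor neurons regardless of the parameter choice, which
#' contradicts the steering amplitudes evolved models must produce.
#'
#' @param w_c,w_g,E,b,E_L_Ca,E_R_ext,w_osc,w_nmj Two-element `c(lo, hi)` ranges.
#' @return Named list of ranges.
#' @export
decode_ranges <- function(w_c = c(0, 5), w_g = c(0, 5), E = c(-5, 5),
                          b = c(-5, 5), E_L_Ca = c(0, 5), E_R_ext = c(0, 5),
                          w_osc = c(0, 5), w_nmj = c(0, 2)) {
  ranges <- list(w_c = w_c, w_g = w_g, E = E, b = b, E_L_Ca = E_L_Ca,
                 E_R_ext = E_R_ext, w_osc = w_osc, w_nmj = w_nmj)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[2] < r[1]) {
      abort(paste0("invalid decode range for ", nm))
    }
  }
  ranges
}

#' Slot layout of a genome for a given connectome
#'
#' The flat genome vector is laid out as: one chemical strength `w_c` per
#' chemical edge, one reversal potential `E` per chemical edge, one gap
#' strength `w_g` per gap junction, one bias `b` per neuron (roster order),
#' then the four globals `E_L_Ca`, `E_R_ext`, `w_osc`, `w_nmj`.
#'
#' @param connectome A `connectome`.
#' @return Tibble with columns `slot`, `kind`, `label`.
#' @export
genome_layout <- function(connectome) {
  nc <- nrow(connectome$chem)
  ng <- nrow(connectome$gap)
  nn <- length(connectome$neurons)
  kinds <- c(rep("w_c", nc), rep("E", nc), rep("w_g", ng), rep("b", nn),
             "E_L_Ca", "E_R_ext", "w_osc", "w_nmj")
  labels <- c(
    paste0("w_c:", connectome$chem$pre, ">", connectome$chem$post),
    paste0("E:", connectome$chem$pre, ">", connectome$chem$post),
    paste0("w_g:", connectome$gap$a, "~", connectome$gap$b),
    paste0("b:", connectome$neurons),
    "E_L_Ca", "E_R_ext", "w_osc", "w_nmj"
  )
  tibble(slot = seq_along(kinds), kind = kinds, label = labels)
}

#' Draw a random genome
#'
#' @param connectome A `connectome` giving the slot count.
#' @param seed Integer seed.
#' @return Numeric vector in \[0, 1\] of length [n_free_parameters()].
#' @export
random_genome <- function(connectome, seed) {
  withr_seed(seed, g <- runif(n_free_parameters(connectome)))
  g
}

#' Decode a genome into a simulatable worm model
#'
#' Applies the affine decode map to every slot and assembles the network,
#' sensory, and neuromuscular parameters. The decode is deterministic and
#' invertible on the stated ranges.
#'
#' @param genome Numeric vector in \[0, 1\], length [n_free_parameters()].
#' @param connectome A `connectome`.
#' @param ranges Decode ranges from [decode_ranges()].
#' @param tau Fixed per-neuron time constant (s); scalar or length-30 vector.
#'   Not evolved.
#' @param sensory Sensory rate constants from [sensory_params()]. The decoded
#'   `E_L_Ca` and `E_R_ext` slots override the corresponding entries.
#' @return A `worm_model` object.
#' @export
decode_genome <- function(genome, connectome, ranges = decode_ranges(),
                          tau = 0.1, sensory = sensory_params()) {
  p <- n_free_parameters(connectome)
  if (length(genome) != p) {
    abort(sprintf("genome length %d does not match the %d free parameters",
                  length(genome), p))
  }
  if (any(!is.finite(genome)) || any(genome < 0 | genome > 1)) {
    abort("genome values must be finite and within [0, 1]")
  }
  aff <- function(x, r) r[1] + x * (r[2] - r[1])
  nc <- nrow(connectome$chem)
  ng <- nrow(connectome$gap)
  nn <- length(connectome$neurons)
  i <- 0
  take <- function(k) {
    out <- genome[(i + 1):(i + k)]
    i <<- i + k
    out
  }
  w_c <- aff(take(nc), ranges$w_c)
  E <- aff(take(nc), ranges$E)
  w_g <- aff(take(ng), ranges$w_g)
  b <- aff(take(nn), ranges$b)
  sensory$E_L_Ca <- aff(take(1), ranges$E_L_Ca)
  sensory$E_R_ext <- aff(take(1), ranges$E_R_ext)
  w_osc <- aff(take(1), ranges$w_osc)
  w_nmj <- aff(take(1), ranges$w_nmj)

  tau <- rep_len(tau, nn)
  if (any(tau <= 0)) abort("time constants must be positive")

  structure(
    list(
      connectome = connectome,
      tau = setNames(tau, connectome$neurons),
      b = setNames(b, connectome$neurons),
      w_c = w_c, E = E, w_g = w_g,
      w_osc = w_osc, w_nmj = w_nmj,
      sensory = sensory,
      genome = genome, ranges = ranges
    ),
    class = "worm_model"
  )
}

#' @export
print.worm_model <- function(x, ...) {
  cat("<worm_model>", length(x$connectome$neurons), "neurons |",
      nrow(x$connectome$chem), "chem,", nrow(x$connectome$gap), "gap edges |",
      "w_osc =", signif(x$w_osc, 3), "| w_nmj =", signif(x$w_nmj, 3), "\n")
  abl <- attr(x$connectome, "ablated")
  if (length(abl)) cat("ablated:", paste(abl, collapse = ", "), "\n")
  invisible(x)
}

#' @export
ablate.worm_model <- function(x, neurons) {
  if (length(neurons) == 0) return(x)
  con <- x$connectome
  bad <- setdiff(neurons, con$neurons)
  if (length(bad) > 0) {
    abort(paste0("unknown neuron name(s): ", paste(bad, collapse = ", ")))
  }
  keep_c <- !(con$chem$pre %in% neurons | con$chem$post %in% neurons)
  keep_g <- !(con$gap$a %in% neurons | con$gap$b %in% neurons)
  x$w_c <- x$w_c[keep_c]
  x$E <- x$E[keep_c]
  x$w_g <- x$w_g[keep_g]
  x$connectome <- ablate(con, neurons)
  x
}

#' The packaged pre-evolved example genome
#'
#' A genome evolved with [run_ga()] on the default connectome scaffold and
#' the conical environment at a larger search budget than the examples use
#' (the evolution seed, configuration and achieved scores are stored in the
#' JSON alongside the values). It skips the expensive stage-A search in
#' examples, tests, and the reproduction script. Desk-scale searches find
#' weaker models than a full-size run: this genome climbs gradients from
#' most initial headings but does not pass the strict successful-model
#' filter of [successful_models()].
#'
#' @return Numeric genome vector (with the stored metadata in attributes).
#' @export
example_genome <- function() {
  path <- system.file("extdata", "genome_evolved_example.json",
                      package = "klinotaxis", mustWork = TRUE)
  load_genome(path)
}

#' Save / load a genome as JSON
#'
#' The JSON records the genome values, the decode-map version, slot layout
#' size, and optionally the per-edge liquid-synapse SDs so a random-walk model
#' can be reconstructed exactly.
#'
#' @param genome Numeric genome vector.
#' @param path Output path.
#' @param sigma Optional per-chemical-edge SD vector (liquid synapses).
#' @param meta Optional named list merged into the JSON record.
#' @return `path`, invisibly.
#' @export
save_genome <- function(genome, path, sigma = NULL, meta = list()) {
  rec <- c(list(decode_map_version = 1L, length = length(genome),
                values = genome, sigma = sigma), meta)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_genome
#' @export
load_genome <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(rec$decode_map_version), 1L)) {
    abort("unsupported genome decode-map version")
  }
  g <- as.numeric(rec$values)
  attr(g, "sigma") <- if (!is.null(rec$sigma)) as.numeric(rec$sigma)
  meta <- rec[setdiff(names(rec), c("decode_map_version", "length",
                                    "values", "sigma"))]
  if (length(meta)) attr(g, "meta") <- meta
  g
}
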