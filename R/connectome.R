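#' The 30-neuron chemotaxis roster
#'
#' Ordered neuron names used throughout the package: the two ASE chemosensory
#' neurons, twelve bilateral interneuron pairs implicated in salt chemotaxis,
#' and the four SMB neck motor neurons that set the amplitude of the sinusoidal
#' head sweep.
#'
#' @return Character vector of length 30.
#' @export
neuron_roster <- function() {
  c(
    "ASEL", "ASER",
    "AIYL", "AIYR", "AIZL", "AIZR", "AIBL", "AIBR", "RIAL", "RIAR",
    "RIML", "RIMR", "RIVL", "RIVR", "AVEL", "AVER", "AVAL", "AVAR",
    "AVBL", "AVBR", "AVDL", "AVDR", "PVCL", "PVCR", "RIBL", "RIBR",
    "SMBDL", "SMBDR", "SMBVL", "SMBVR"
  )
}

SENSORY_NEURONS <- c("ASEL", "ASER")
MOTOR_NEURONS <- c("SMBDL", "SMBDR", "SMBVL", "SMBVR")
DORSAL_MOTOR <- c("SMBDL", "SMBDR")
VENTRAL_MOTOR <- c("SMBVL", "SMBVR")

#' Load a connectome edge list
#'
#' Reads a CSV with columns `pre`, `post`, `type` (`"chem"` for directed
#' chemical synapses, `"gap"` for undirected electrical couplings) over the
#' 30-neuron roster and validates it. Gap junctions are stored once per pair
#' and treated symmetrically; self-edges are rejected.
#'
#' The default file shipped with the package
#' (`connectome_synthetic.csv`) is a synthetic scaffold compiled from
#' qualitative descriptions of the C. elegans chemotaxis circuit, sized so the
#' evolved model has exactly 463 free parameters. It is deliberately
#' user-editable: point `path` at your own CSV to use a different wiring.
#'
#' @param path Path to the edge-list CSV. Defaults to the packaged scaffold.
#' @return A `connectome` object: list with `neurons` (roster), `chem`
#'   (tibble `pre`, `post`), and `gap` (tibble `a`, `b`).
#' @export
load_connectome <- function(path = NULL) {
  path <- path %||% system.file("extdata", "connectome_synthetic.csv",
                                package = "klinotaxis", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pre", "post", "type") %in% names(df))) {
    abort("connectome CSV must have columns pre, post, type")
  }
  roster <- neuron_roster()
  bad <- setdiff(unique(c(df$pre, df$post)), roster)
  if (length(bad) > 0) {
    abort(paste0("unknown neuron name(s) in connectome: ", paste(bad, collapse = ", ")))
  }
  if (any(df$pre == df$post)) abort("self-edges are not allowed")
  if (!all(df$type %in% c("chem", "gap"))) abort("type must be 'chem' or 'gap'")

  chem <- df[df$type == "chem", c("pre", "post")]
  if (anyDuplicated(paste(chem$pre, chem$post))) abort("duplicate chemical edges")
  gap <- df[df$type == "gap", c("pre", "post")]
  if (nrow(gap) > 0) {
    gk <- t(apply(as.matrix(gap), 1, sort))
    if (anyDuplicated(paste(gk[, 1], gk[, 2]))) abort("duplicate gap edges")
    gap <- tibble(a = gk[, 1], b = gk[, 2])
  } else {
    gap <- tibble(a = character(), b = character())
  }
  new_connectome(roster, as_tibble(chem), gap)
}

new_connectome <- function(neurons, chem, gap) {
  structure(list(neurons = neurons, chem = chem, gap = gap),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", length(x$neurons), "neurons,",
      nrow(x$chem), "chemical edges,", nrow(x$gap), "gap junctions\n")
  cat("free parameters when evolved:", n_free_parameters(x), "\n")
  invisible(x)
}

#' Number of evolvable parameters implied by a connectome
#'
#' One strength and one reversal potential per chemical edge, one strength per
#' gap junction, one bias per neuron, plus the four global parameters
#' (`E_L_Ca`, `E_R_ext`, `w_osc`, `w_nmj`). Neuron time constants are fixed by
#' configuration and not counted.
#'
#' @param connectome A `connectome`.
#' @return Integer parameter count.
#' @export
n_free_parameters <- function(connectome) {
  2L * nrow(connectome$chem) + nrow(connectome$gap) +
    length(connectome$neurons) + 4L
}

#' Remove neurons from the circuit (simulated laser ablation)
#'
#' Structural removal: every chemical edge and gap junction incident to an
#' ablated neuron is deleted, the neuron's voltage is clamped to rest, and its
#' output is excluded from the neuromuscular sum. Ablation is idempotent and
#' commutes across neuron sets. The ablated names are accumulated in the
#' `ablated` attribute so repeated calls compose.
#'
#' @param x A `connectome` or a decoded `worm_model`.
#' @param neurons Character vector of neuron names to remove (may be empty).
#' @return The modified object with an `ablated` attribute on its connectome.
#' @export
ablate <- function(x, neurons) UseMethod("ablate")

#' @export
ablate.connectome <- function(x, neurons) {
  connectome <- x
  if (length(neurons) == 0) return(connectome)
  bad <- setdiff(neurons, connectome$neurons)
  if (length(bad) > 0) {
    abort(paste0("unknown neuron name(s): ", paste(bad, collapse = ", ")))
  }
  out <- connectome
  out$chem <- out$chem[!(out$chem$pre %in% neurons | out$chem$post %in% neurons), ]
  out$gap <- out$gap[!(out$gap$a %in% neurons | out$gap$b %in% neurons), ]
  attr(out, "ablated") <- sort(union(attr(connectome, "ablated"), neurons))
  out
}

#' Degree-free random rewiring control
#'
#' Generates a random network with the same neurons and the same total number
#' of chemical and gap edges, but a randomly drawn connection structure. Only
#' the edge totals are preserved, not the degree sequence. Self-edges are
#' excluded and gap symmetry (one undirected pair per junction) is maintained.
#'
#' @param connectome A `connectome` to use as the size template.
#' @param seed Integer seed for reproducibility.
#' @return A new `connectome`.
#' @export
randomize_connectome <- function(connectome, seed) {
  stopifnot(inherits(connectome, "connectome"))
  roster <- connectome$neurons
  n <- length(roster)
  withr_seed(seed, {
    # directed pairs, no self-edges
    all_dir <- expand.grid(pre = seq_len(n), post = seq_len(n))
    all_dir <- all_dir[all_dir$pre != all_dir$post, ]
    pick <- sample(nrow(all_dir), nrow(connectome$chem))
    chem <- tibble(pre = roster[all_dir$pre[pick]], post = roster[all_dir$post[pick]])
    und <- t(utils::combn(n, 2))
    gpick <- sample(nrow(und), nrow(connectome$gap))
    gap <- tibble(a = roster[und[gpick, 1]], b = roster[und[gpick, 2]])
  })
  new_connectome(roster, chem, gap)
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
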