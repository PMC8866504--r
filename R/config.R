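run_config_defaults <- function() {
  list(
    env = list(kind = "conical", kappa = 1, r_max = 6, peak = c(0, 0),
               literal = FALSE, N0 = 0.55, D_c = 1e-5, d_c = 0.2,
               t0_env = 3600, level = 1),
    chemotaxis_duration = 800,
    random_walk_duration = 1200,
    chemotaxis_runs = 50,
    random_walk_runs = 500,
    dt = 0.01,
    seed = 1,
    start_radius = 4.5,
    capture_radius = 0.1,
    liquid_enabled = FALSE,
    sharp_turns_enabled = FALSE,
    tau = 0.1,
    out_dir = "results",
    connectome = NULL,
    genome = NULL
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills in defaults for missing keys, and rejects unknown
#' keys and invalid values (non-positive durations, counts, or `dt`). An
#' empty or absent body yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  normalize_config(raw)
}

#' @rdname load_config
#' @param config A (possibly partial) configuration list.
#' @export
normalize_config <- function(config = list()) {
  defaults <- run_config_defaults()
  # YAML null fields mean "use the default"
  config[vapply(config, is.null, logical(1))] <- NULL
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$env)) {
    bad_env <- setdiff(names(config$env), names(defaults$env))
    if (length(bad_env) > 0) {
      abort(paste0("unknown config key(s): ",
                   paste0("env.", bad_env, collapse = ", ")))
    }
    config$env <- utils::modifyList(defaults$env, config$env)
  }
  out <- utils::modifyList(defaults, config)
  for (key in c("chemotaxis_duration", "random_walk_duration", "dt",
                "start_radius", "capture_radius")) {
    if (!is.numeric(out[[key]]) || out[[key]] <= 0) {
      abort(paste0("config field '", key, "' must be a positive number"))
    }
  }
  for (key in c("chemotaxis_runs", "random_walk_runs")) {
    if (out[[key]] < 1) abort(paste0("config field '", key, "' must be >= 1"))
  }
  if (!out$env$kind %in% c("conical", "gaussian", "isotropic")) {
    abort("env.kind must be conical, gaussian or isotropic")
  }
  structure(out, class = "run_config")
}

#' Build the environment described by a configuration
#'
#' @param config A `run_config`.
#' @return An `env_spec`.
#' @export
config_environment <- function(config) {
  e <- config$env
  switch(e$kind,
    conical = environment_conical(e$kappa, unlist(e$peak), e$r_max, e$literal),
    gaussian = environment_gaussian(e$N0, e$D_c, e$d_c, e$t0_env,
                                    unlist(e$peak)),
    isotropic = environment_isotropic(e$level)
  )
}

#' Write a run config back to YAML
#'
#' `save_config(load_config(x))` round-trips to the normalized form.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce and audit a run: a hash of the
#' normalized configuration, the seeds, the package version, the connectome
#' size and the implied free-parameter count (the evolved-architecture target
#' is 463), and an inventory of output files. The output directory is created
#' if missing.
#'
#' @param config A `run_config`.
#' @param connectome The `connectome` used.
#' @param path Output JSON path.
#' @param files Character vector of produced files.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, connectome, path, files = character(),
                           extra = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("klinotaxis")),
    config_hash = rlang::hash(unclass(normalize_config(unclass(config)))),
    config = unclass(config),
    seed = config$seed,
    n_neurons = length(connectome$neurons),
    n_chem_edges = nrow(connectome$chem),
    n_gap_edges = nrow(connectome$gap),
    n_free_parameters = n_free_parameters(connectome),
    free_parameter_target = 463L,
    files = as.list(files)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
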