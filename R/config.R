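#' Full default run configuration
#'
#' A nested list mirroring the parameter constructors: `geometry`,
#' `filaments`, `lattice`, `springs`, `rates`, `titin`, `solver`,
#' `activation`, `protocol`, `scaling`, plus `seed` and `binding_window`.
#' Everything is plain scalars, so the configuration round-trips through
#' YAML unchanged.
#'
#' @export
default_config <- function() {
  drop_class <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, logical(1))]
  }
  proto <- drop_class(workloop_protocol())
  proto$prescribed_trace <- NULL
  proto$period <- NULL
  springs <- drop_class(spring_params())
  springs$theta_pre <- NULL  # derived from the degree fields
  springs$theta_post <- NULL
  list(
    geometry = drop_class(geometry_config()),
    filaments = drop_class(filament_params()),
    lattice = list(face_spacing = 15, lattice_class = "invertebrate_flight",
                   r_sum = 12.5),
    springs = springs,
    rates = drop_class(rate_params()),
    titin = drop_class(titin_params()),
    solver = drop_class(solver_config()),
    activation = drop_class(activation_params()),
    protocol = proto,
    scaling = drop_class(scaling_params()),
    binding_window = 16,
    seed = 1L
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      rlang::abort(sprintf("unknown configuration key `%s`", key),
                   class = "myolattice_config_error")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        rlang::abort(sprintf("configuration key `%s` must be a section", key),
                     class = "myolattice_config_error")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load, validate and default a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()], rejects unknown
#' keys, and validates every section through its parameter constructor. An
#' empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return validated configuration list of class `myolattice_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("configuration file `%s` does not exist", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  build_from_config(cfg) # constructors perform all validation
  structure(cfg, class = c("myolattice_config", "list"))
}

#' Instantiate model objects from a configuration
#'
#' @param cfg a configuration list (see [default_config()]).
#' @return list with `state`, `protocol`, `activation`, `scaling`, `seed`.
#' @export
build_from_config <- function(cfg) {
  geometry <- do.call(geometry_config, cfg$geometry)
  filaments <- do.call(filament_params, cfg$filaments)
  lattice <- do.call(lattice_state, cfg$lattice)
  springs <- do.call(spring_params, cfg$springs)
  rates <- do.call(rate_params, cfg$rates)
  titin <- do.call(titin_params, cfg$titin)
  solver <- do.call(solver_config, cfg$solver)
  activation <- do.call(activation_params, cfg$activation)
  protocol <- do.call(workloop_protocol, cfg$protocol)
  scaling <- do.call(scaling_params, cfg$scaling)
  state <- build_half_sarcomere(geometry, filaments, lattice, springs, rates,
                                titin, solver,
                                binding_window = cfg$binding_window)
  list(state = state, protocol = protocol, activation = activation,
       scaling = scaling, seed = as.integer(cfg$seed))
}

#' @rdname load_config
#' @param file output YAML path.
#' @export
save_config <- function(cfg, file) {
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Write simulation results with a run manifest
#'
#' Writes the per-timestep trace (for `workloop_result` / `isometric_result`)
#' or the condition table (for sweep tibbles) as CSV with a deterministic
#' column order, plus a JSON manifest holding the seed, a configuration hash
#' and summary statistics, so a run can be identified and reproduced.
#'
#' @param result a `workloop_result`, `isometric_result`, or tibble.
#' @param dir output directory (created if needed).
#' @param name basename for the output files.
#' @param config optional configuration list stored (hashed) in the manifest.
#' @return invisibly, the paths written.
#' @export
write_result <- function(result, dir, name = "run", config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  manifest_path <- file.path(dir, paste0(name, "_manifest.json"))
  manifest <- list(name = name, package = "myolattice",
                   config_hash = if (!is.null(config)) rlang::hash(config) else NA,
                   config = config)
  if (inherits(result, "workloop_result")) {
    utils::write.csv(
      result$trace[, c("time", "strain", "stress", "permissiveness",
                       "face_spacing", "force", "n_bound", "n_strong")],
      csv, row.names = FALSE)
    manifest$seed <- result$seed
    manifest$work_mean <- result$work_mean
    manifest$work_sd <- result$work_sd
    manifest$per_cycle_work <- result$per_cycle_work
  } else if (inherits(result, "isometric_result")) {
    utils::write.csv(result$trace, csv, row.names = FALSE)
    manifest$seed <- result$seed
    manifest$passive_force <- result$passive_force
  } else {
    utils::write.csv(as.data.frame(result), csv, row.names = FALSE)
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(csv = csv, manifest = manifest_path))
}
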