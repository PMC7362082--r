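#' Read a fibrinet configuration file
#'
#' Configuration files are YAML with up to four sections — `parameters`,
#' `fiber`, `clot`, `simulation` — whose keys are the arguments of
#' [fibrin_params()], [fiber_geometry()], [clot_params()] and
#' [sim_controls()]. Missing sections or keys fall back to the defaults;
#' unknown keys are reported as warnings, never errors, so configs stay
#' forward-compatible. A commented example ships at
#' `system.file("extdata", "default_config.yaml", package = "fibrinet")`.
#'
#' @param path Path to a YAML config file, or `NULL` for an all-defaults
#'   configuration.
#' @return A list with elements `parameters` (`fibrin_params`), `fiber`
#'   (`fiber_geometry`), `clot` (`clot_params`) and `simulation`
#'   (`sim_controls`).
#' @examples
#' cfg <- read_fibrin_config(NULL)
#' cfg$parameters$k3
#' @export
read_fibrin_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path))
    }
    raw <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) abort(sprintf("failed to parse config '%s': %s",
                                        path, conditionMessage(e)))
    )
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) abort(sprintf("config '%s' is not a key/value mapping", path))
  }

  known_sections <- c("parameters", "fiber", "clot", "simulation")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown config section(s): %s",
                 paste(unknown, collapse = ", ")))
  }

  build <- function(section, constructor) {
    vals <- raw[[section]] %||% list()
    formal_names <- names(formals(constructor))
    unknown_keys <- setdiff(names(vals), formal_names)
    if (length(unknown_keys) > 0) {
      warn(sprintf("ignoring unknown key(s) in [%s]: %s",
                   section, paste(unknown_keys, collapse = ", ")))
      vals <- vals[intersect(names(vals), formal_names)]
    }
    do.call(constructor, vals)
  }

  list(
    parameters = build("parameters", fibrin_params),
    fiber      = build("fiber", fiber_geometry),
    clot       = build("clot", clot_params),
    simulation = build("simulation", sim_controls)
  )
}

#' Write a fibrinet configuration file
#'
#' Serialises a configuration (as returned by [read_fibrin_config()]) back to
#' YAML. Numbers are written with 17 significant digits so a save/load
#' round-trip reproduces every field bit-exactly.
#'
#' @param config A list with elements `parameters`, `fiber`, `clot`,
#'   `simulation` (each may also be passed individually via the component
#'   constructors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fibrin_config <- function(config, path) {
  out <- list(
    parameters = unclass(config$parameters),
    fiber      = unclass(config$fiber),
    clot       = unclass(config$clot),
    simulation = unclass(config$simulation)
  )
  # drop NULLs (e.g. unset random_seed); Inf round-trips as YAML .inf
  out <- lapply(out, function(sec) sec[!vapply(sec, is.null, logical(1))])
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
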