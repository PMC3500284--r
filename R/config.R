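# Run configuration: every tunable constant in one nested list that
# round-trips losslessly through YAML.  Unknown keys are rejected.

#' Default run configuration
#'
#' Nested list with all tunable parameters: energy weights and term
#' constants, move category weights and amplitudes, stage schedules,
#' temperature control, loop-builder parameters and pool settings.
#'
#' @return nested configuration list
#' @export
defaultConfig <- function() {
  list(
    weights = as.list(weightSet()),
    energy = energyConstants(),
    moves = list(
      category_weights = list(
        assembly = list(add = 0.25, remove = 0.05, swap = 0.10,
                        single_sse = 0.30, sse_pair = 0.15, domain = 0.15),
        refinement = list(single_sse = 0.50, sse_pair = 0.25,
                          domain = 0.15, resize = 0.10)),
      amplitudes = MOVE_AMPLITUDES),
    schedules = list(
      assembly = list(max_steps = 5000L, max_nonimproving = 1000L),
      refinement = list(max_steps = 2000L, max_nonimproving = 400L)),
    temperature = list(t0 = 500, adjust_every = 10L, start_target = 0.5,
                       end_target = 0.2, factor_up = 1.05, factor_down = 0.95,
                       t_min = 1e-3, t_max = 1e6, k = 1),
    loops = list(n_candidates = 20L, ccd_tolerance = 0.08,
                 max_sweeps = 200L, force_rounds = 5L),
    pool = list(threshold = 0.5, min_helix = 5L, min_strand = 3L,
                refine_steps = 1000L))
}

checkKeys <- function(x, ref, path = "") {
  if (!is.list(x) || !is.list(ref)) return(invisible(NULL))
  bad <- setdiff(names(x), names(ref))
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s", ": ",
         paste0(path, bad, collapse = ", "))
  for (k in names(x))
    if (is.list(ref[[k]])) checkKeys(x[[k]], ref[[k]], paste0(path, k, "."))
  invisible(NULL)
}

#' Read and write run configurations
#'
#' Configurations are stored as YAML.  `readConfig` overlays the file's
#' values on the defaults and rejects unknown keys; the round trip
#' through `writeConfig`/`readConfig` is lossless.
#'
#' @param path YAML file path
#' @return `readConfig`: a full configuration list
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- defaultConfig()
  if (!is.null(user)) checkKeys(user, ref)
  mergeConfig(ref, user)
}

mergeConfig <- function(ref, user) {
  if (is.null(user)) return(ref)
  for (k in names(user)) {
    ref[[k]] <- if (is.list(ref[[k]]) && is.list(user[[k]]))
      mergeConfig(ref[[k]], user[[k]])
    else if (!is.list(ref[[k]]) && is.list(user[[k]]))
      unlist(user[[k]])  # named vectors come back from YAML as lists
    else user[[k]]
  }
  ref
}

#' @rdname readConfig
#' @param config a configuration list
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(listifyVectors(config), path)
  invisible(path)
}

# named atomic vectors lose their names through YAML sequences; write
# them as maps instead
listifyVectors <- function(x) {
  if (is.list(x)) return(lapply(x, listifyVectors))
  if (is.atomic(x) && !is.null(names(x)) && length(x) > 1) as.list(x) else x
}

configWeights <- function(config) {
  do.call(weightSet, as.list(unlist(config$weights)))
}

configConstants <- function(config) {
  const <- energyConstants()
  for (k in names(config$energy)) const[[k]] <- config$energy[[k]]
  const
}
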