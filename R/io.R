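#' Default run configuration
#'
#' The full configuration consumed by the simulation/analysis drivers:
#' circuit composition and plasticity state, stimulation protocol, and
#' the presynaptic parameter sets of the named synapse classes (mf_grc,
#' mf_goc, pf_goc, aa_goc, goc_grc). All values default to the
#' granular-layer model settings (mf-GrC p = 0.42, tau_rec = 8 ms,
#' 6 release sites, ...).
#'
#' @return Nested list of defaults (class `run_config`).
#' @export
default_config <- function() {
  rel <- synapse_classes()
  structure(list(
    circuit = list(n_mf = 2L, n_goc = 2L, n_release_sites = 6L,
                   stochastic = TRUE,
                   plasticity = list(mf_grc = "control",
                                     goc_grc = "control"),
                   plasticity_fraction = 0.5,
                   temperature = 30, seed = 1L),
    protocol = list(type = "burst", frequency = 100, n_pulses = 5L,
                    n_trials = 10L),
    synapses = lapply(rel, function(r)
      list(p_init = r$p_init, tau_rec = r$tau_rec,
           tau_facil = r$tau_facil, tau_inact = r$tau_inact,
           n_sites = r$n_sites))
  ), class = "run_config")
}

merge_validate <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key '%s' must be a section", full))
      defaults[[key]] <- merge_validate(defaults[[key]], user[[key]],
                                        full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (with the
#' offending key named) and fills every omitted setting with the model
#' default, so a minimal file yields the full parameter set.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A complete validated configuration (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(unclass(default_config()), user)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#' @param config a `run_config` list.
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a trace set to tidy CSV with a JSON sidecar
#'
#' The CSV holds columns `trial`, `time_ms`, `value`; the mandatory
#' sidecar `<path>.json` carries the modality, time step, stimulus
#' times, protocol metadata and seed, so the pair round-trips losslessly.
#'
#' @param ts a [trace_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  nt <- ncol(ts$traces)
  df <- data.frame(
    trial = rep(seq_len(nt), each = length(ts$time)),
    time_ms = rep(ts$time, nt),
    value = as.vector(ts$traces))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(modality = ts$modality, dt = ts$dt,
               stim_times = ts$stim_times, protocol = ts$protocol,
               seed = ts$seed, n_trials = nt,
               n_samples = length(ts$time))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#'
#' @param path CSV path; `<path>.json` must exist.
#' @return A [trace_set()].
#' @export
read_traces <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing metadata sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  stopifnot(all(c("trial", "time_ms", "value") %in% names(df)))
  trials <- sort(unique(df$trial))
  if (length(trials) == 0L) {
    return(trace_set(numeric(0), matrix(numeric(0), 0, 0),
                     side$modality, stim_times = numeric(0),
                     protocol = as.list(side$protocol), seed = side$seed))
  }
  time <- df$time_ms[df$trial == trials[1]]
  tr <- vapply(trials, function(k) df$value[df$trial == k],
               numeric(length(time)))
  trace_set(time, tr, side$modality,
            stim_times = as.numeric(side$stim_times %||% numeric(0)),
            protocol = as.list(side$protocol), seed = side$seed)
}

#' Build a run manifest
#'
#' Records everything needed to re-run a pipeline step bit-identically:
#' the command label, the fully resolved configuration, the seeds, the
#' package version and the output paths.
#'
#' @param command command label.
#' @param config resolved configuration list.
#' @param seed seed(s) used.
#' @param outputs character vector of output paths.
#' @return Manifest list (class `run_manifest`).
#' @export
run_manifest <- function(command, config, seed, outputs = character(0)) {
  structure(list(
    command = command,
    config = if (inherits(config, "run_config")) unclass(config)
             else config,
    seed = seed,
    package_version = as.character(utils::packageVersion("grcgain")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs), class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
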