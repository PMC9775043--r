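#' Frequency sweep of burst transmission
#'
#' Runs the burst protocol at each frequency and measures the burst
#' metrics, returning both the raw per-frequency metrics and the derived
#' gain curve: the compound gain index (spiking regime) or the min-max
#' normalized average maximum depolarization (subthreshold regime).
#'
#' @param circuit a [wire_circuit()] result.
#' @param freqs burst frequencies (Hz), increasing.
#' @param n_trials trials per frequency.
#' @param kind `"cGI"` or `"amd"`.
#' @param seed base seed; each frequency uses an offset stream.
#' @param ... passed to [run_burst()].
#' @return List with `metrics` (data.frame) and `curve`
#'   (a [gain_curve()]).
#' @export
run_gain_sweep <- function(circuit, freqs = c(10, 20, 50, 100, 200, 500),
                           n_trials = 10L, kind = c("cGI", "amd"),
                           seed = NULL, ...) {
  kind <- match.arg(kind)
  stopifnot(all(diff(freqs) > 0))
  seed <- seed %||% circuit$config$seed
  rows <- vector("list", length(freqs))
  for (k in seq_along(freqs)) {
    ts <- run_burst(circuit, burst_protocol(freqs[k],
                                            n_trials = n_trials),
                    seed = seed + 10000L * k, ...)
    m <- burst_metrics(ts)
    rows[[k]] <- data.frame(frequency = freqs[k], sc = m$sc, sp = m$sp,
                            fssd = m$fssd, amd = m$amd)
  }
  metrics <- do.call(rbind, rows)
  curve <- if (kind == "cGI") {
    normalize_and_compound(metrics)
  } else {
    gain_curve(metrics$frequency, minmax01(metrics$amd), "amd")
  }
  list(metrics = metrics, curve = curve)
}

#' Gain curves under control, LTP and LTD
#'
#' Convenience driver for the plasticity comparison: rebuilds the circuit
#' with the requested plasticity state per condition (identical wiring
#' and seeds otherwise) and sweeps the gain curve.
#'
#' @param n_mf,n_goc circuit composition.
#' @param freqs frequencies (Hz).
#' @param n_trials trials per frequency.
#' @param kind `"cGI"` or `"amd"`.
#' @param gabaergic logical; apply the same-sign plasticity to the
#'   GABAergic Golgi-granule synapse as well as the excitatory one.
#' @param seed base seed.
#' @param stochastic stochastic mf-GrC release.
#' @param modes plasticity modes to run.
#' @param ... passed to [run_gain_sweep()].
#' @return Named list (per mode) of [run_gain_sweep()] results.
#' @export
plasticity_gain_curves <- function(n_mf, n_goc,
                                   freqs = c(10, 20, 50, 100, 200, 500),
                                   n_trials = 10L,
                                   kind = c("cGI", "amd"),
                                   gabaergic = FALSE, seed = 1L,
                                   stochastic = TRUE,
                                   modes = c("control", "ltp", "ltd"),
                                   ...) {
  kind <- match.arg(kind)
  out <- list()
  for (mode in modes) {
    plast <- list(mf_grc = mode,
                  goc_grc = if (gabaergic) mode else "control")
    cfg <- circuit_config(n_mf = n_mf, n_goc = n_goc,
                          stochastic = stochastic, plasticity = plast,
                          seed = seed)
    circ <- wire_circuit(cfg)
    out[[mode]] <- run_gain_sweep(circ, freqs = freqs,
                                  n_trials = n_trials, kind = kind,
                                  seed = seed, ...)
  }
  out
}
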