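#' Microcircuit configuration
#'
#' Describes the simplified granular-layer circuit: one granule cell
#' receiving `n_mf` mossy fibers (one per dendrite, up to 4) and `n_goc`
#' Golgi cells (feedforward mf drive and feedback via parallel-fiber and
#' ascending-axon synapses; GABAergic Golgi-granule synapses assigned to
#' dendrites round-robin). Long-term plasticity is a release-probability
#' scaling applied per synapse class (`mf_grc`, `goc_grc`).
#'
#' @param n_mf number of mossy fibers (1-4).
#' @param n_goc number of Golgi cells (0-4).
#' @param n_release_sites release sites per synapse; default 6.
#' @param stochastic logical; stochastic (all-or-none per site) release at
#'   the mf-GrC synapse.
#' @param plasticity named list of plasticity modes per synapse class,
#'   e.g. `list(mf_grc = "ltp", goc_grc = "control")`.
#' @param plasticity_fraction release-probability scaling fraction.
#' @param temperature simulation temperature (deg C).
#' @param seed base RNG seed recorded in outputs.
#' @param calibrate_mf_goc logical; calibrate the mf-GoC conductance to a
#'   -66 pA single-stimulus EPSC at wiring time.
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(n_mf = 2, n_goc = 2, n_release_sites = 6L,
                           stochastic = TRUE,
                           plasticity = list(mf_grc = "control",
                                             goc_grc = "control"),
                           plasticity_fraction = 0.5,
                           temperature = 30, seed = 1L,
                           calibrate_mf_goc = TRUE) {
  if (!(n_mf %in% 1:4)) stop("'n_mf' must be in 1..4")
  if (!(n_goc %in% 0:4)) stop("'n_goc' must be in 0..4")
  stopifnot(n_release_sites >= 1)
  structure(list(n_mf = as.integer(n_mf), n_goc = as.integer(n_goc),
                 n_release_sites = as.integer(n_release_sites),
                 stochastic = stochastic, plasticity = plasticity,
                 plasticity_fraction = plasticity_fraction,
                 temperature = temperature, seed = as.integer(seed),
                 calibrate_mf_goc = calibrate_mf_goc),
            class = "circuit_config")
}

#' The four analyzed input configurations
#'
#' Named (mossy fiber, Golgi cell) count presets spanning the excitatory
#' range with an approximately constant inhibitory complement:
#' (1 mf, 3 GoC), (2 mf, 2 GoC), (3 mf, 2 GoC), (4 mf, 3 GoC).
#'
#' @return Named list of c(n_mf, n_goc) pairs.
#' @export
circuit_presets <- function() {
  list(mf1_goc3 = c(n_mf = 1L, n_goc = 3L),
       mf2_goc2 = c(n_mf = 2L, n_goc = 2L),
       mf3_goc2 = c(n_mf = 3L, n_goc = 2L),
       mf4_goc3 = c(n_mf = 4L, n_goc = 3L))
}

#' Burst stimulation protocol
#'
#' Five-pulse mossy-fiber bursts at a set frequency, repeated over
#' independent trials (experimentally delivered at 0.1 Hz, i.e. a 10 s
#' inter-trial interval; trials are simulated independently).
#'
#' @param frequency intra-burst frequency (Hz), 10-500.
#' @param n_pulses pulses per burst; default 5.
#' @param n_trials repetitions; default 10.
#' @param trial_interval_s nominal inter-trial interval (s); metadata.
#' @return An object of class `burst_protocol`.
#' @export
burst_protocol <- function(frequency, n_pulses = 5L, n_trials = 10L,
                           trial_interval_s = 10) {
  stopifnot(frequency > 0, n_pulses >= 1, n_trials >= 1)
  structure(list(frequency = frequency, n_pulses = as.integer(n_pulses),
                 n_trials = as.integer(n_trials),
                 trial_interval_s = trial_interval_s),
            class = "burst_protocol")
}

#' Theta-burst stimulation protocol
#'
#' @param pulses_per_burst pulses per burst; default 10.
#' @param intra_burst_freq within-burst frequency (Hz); default 100.
#' @param n_bursts bursts; default 8.
#' @param burst_interval burst onset spacing (ms); default 250.
#' @return An object of class `tbs_protocol`.
#' @export
tbs_protocol <- function(pulses_per_burst = 10L, intra_burst_freq = 100,
                         n_bursts = 8L, burst_interval = 250) {
  structure(list(pulses_per_burst = as.integer(pulses_per_burst),
                 intra_burst_freq = intra_burst_freq,
                 n_bursts = as.integer(n_bursts),
                 burst_interval = burst_interval),
            class = "tbs_protocol")
}

#' Stimulus times of a TBS protocol
#' @param protocol a [tbs_protocol()].
#' @param t0 time of the first pulse (ms).
#' @return Vector of stimulus times (ms).
#' @export
tbs_times <- function(protocol = tbs_protocol(), t0 = 0) {
  within_burst <- (seq_len(protocol$pulses_per_burst) - 1L) *
    1000 / protocol$intra_burst_freq
  onsets <- (seq_len(protocol$n_bursts) - 1L) * protocol$burst_interval
  sort(as.vector(outer(within_burst, onsets, `+`))) + t0
}

#' Repeated-trial trace container
#'
#' @param time uniform time base (ms).
#' @param traces matrix, one column per trial.
#' @param modality `"voltage"` (mV) or `"current"` (pA).
#' @param stim_times stimulus times (ms).
#' @param protocol protocol metadata (list).
#' @param seed RNG seed used.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(time, traces, modality = c("voltage", "current"),
                      stim_times = numeric(0), protocol = list(),
                      seed = NA_integer_) {
  modality <- match.arg(modality)
  traces <- as.matrix(traces)
  stopifnot(nrow(traces) == length(time))
  if (length(time) > 1) {
    dts <- diff(time)
    if (max(abs(dts - dts[1])) > 1e-9 * max(abs(dts)))
      stop("non-uniform time base")
  }
  structure(list(time = time, traces = traces, modality = modality,
                 dt = if (length(time) > 1) time[2] - time[1] else NA_real_,
                 stim_times = stim_times, protocol = protocol,
                 seed = seed),
            class = "trace_set")
}

#' @exportS3Method base::print
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d trials x %d samples (%s), dt = %g ms>\n",
              ncol(x$traces), nrow(x$traces), x$modality, x$dt))
  invisible(x)
}

# --- synapse assembly -------------------------------------------------------

# Flatten a kinetic scheme (already temperature-adapted) for the C++ core,
# computing the cached matrix-exponential propagator for zero transmitter.
prep_receptor <- function(scheme, gmax_pS, dt) {
  tr <- scheme$transitions
  idx <- function(v) match(v, scheme$state_names) - 1L
  Q0 <- scheme_rate_matrix(scheme, 0)
  P0 <- as.matrix(Matrix::expm(Matrix::Matrix(t(Q0) * dt)))
  list(ns = length(scheme$state_names),
       from = idx(tr$from), to = idx(tr$to),
       rate = as.numeric(tr$rate),
       drive = match(tr$drive, c("const", "T", "S")) - 1L,
       open = idx(scheme$open_states),
       KB = scheme$KB,
       gmax = gmax_pS * 1e-6,            # pS -> uS
       erev = scheme$Vrev,
       mg = isTRUE(scheme$mg_block), mg_conc = scheme$mg,
       diffusion_only = identical(scheme$transmitter, "diffusion"),
       P0 = P0)
}

prep_synapse <- function(class, pre_kind, pre_index, post_cell, post_comp,
                         release, receptors, trans, dt, stochastic,
                         delay = 1) {
  list(class = class,
       post_cell = post_cell, post_comp = post_comp,
       pre_kind = pre_kind, pre_index = pre_index, delay = delay,
       p = release$p_init, tau_rec = release$tau_rec,
       tau_facil = release$tau_facil, tau_inact = release$tau_inact,
       n_sites = release$n_sites, stochastic = stochastic,
       Ts_max = trans$Ts_max, Td_max = trans$Td_max,
       pulse_dur = trans$pulse_duration, diff_tau = trans$diff_tau,
       receptors = receptors)
}

#' Wire the granular-layer microcircuit
#'
#' Instantiates the granule cell, the Golgi cells and the synapse classes
#' (mf-GrC AMPA+NMDA with gmax 1200 and 18800 pS split over release
#' sites; mf-GoC calibrated to a -66 pA EPSC; parallel-fiber GoC synapses
#' with AMPA, NMDA and kainate receptors at release probability 0.1;
#' ascending-axon GoC synapses with doubled conductance; GABAergic
#' Golgi-granule synapses with fast+slow pathways). All synapses use a
#' 1 ms transmission delay. Plasticity modes in the configuration scale
#' the release probabilities of the mf-GrC and GoC-GrC classes.
#'
#' @param config a [circuit_config()].
#' @param dt integration step (ms), fixed at wiring time because the
#'   receptor resting propagators are precomputed for it.
#' @return An object of class `circuit`.
#' @export
wire_circuit <- function(config, dt = 0.025) {
  stopifnot(inherits(config, "circuit_config"))
  schemes <- lapply(build_default_schemes(), adapt_scheme_temperature,
                    t_sim = config$temperature)
  fdiff <- 1 / q10_scale(1, 1.3, 37, config$temperature)
  rel <- synapse_classes(config$n_release_sites)
  frac <- config$plasticity_fraction
  mode_of <- function(cls) {
    m <- config$plasticity[[cls]]
    if (is.null(m)) "control" else m
  }
  rel$mf_grc <- apply_plasticity(rel$mf_grc,
                                 plasticity_mode(mode_of("mf_grc"), frac))
  rel$goc_grc <- apply_plasticity(rel$goc_grc,
                                  plasticity_mode(mode_of("goc_grc"), frac))

  # glutamate transient surrogates calibrated so a paired-mossy-fiber
  # stimulus depolarizes the granule cell by ~11 mV (the measured EPSP)
  glu_trans <- transmitter_params(Ts_max = 0.6, Td_max = 0.18,
                                  pulse_duration = 1.0,
                                  diff_tau = 1.2 * fdiff)
  gaba_trans <- transmitter_params(Ts_max = 1.0, Td_max = 0.2,
                                   pulse_duration = 1.0,
                                   diff_tau = 5.0 * fdiff)

  grc <- build_grc()
  grc$temperature <- config$temperature
  goc <- build_goc()
  goc$temperature <- config$temperature
  cells <- c(list(grc), rep(list(goc), config$n_goc))
  names(cells) <- c("grc", if (config$n_goc > 0)
    sprintf("goc%d", seq_len(config$n_goc)))

  tips <- sprintf("dend%d_4", 1:4)
  syn <- list()
  rc <- function(which, gmax) prep_receptor(schemes[[which]], gmax, dt)
  # mf -> GrC, one synapse per dendrite tip, mf i on dendrite i
  for (i in seq_len(config$n_mf)) {
    syn[[length(syn) + 1L]] <- prep_synapse(
      "mf_grc", 0L, i - 1L, 0L, tips[i], rel$mf_grc,
      list(rc("ampa", 1200), rc("nmda", 18800)),
      glu_trans, dt, config$stochastic)
  }
  # mf -> GoC (every mf onto every GoC, basolateral dendrite)
  mf_goc_scale <- if (config$calibrate_mf_goc)
    calibrate_mf_goc_scale(config, dt) else 1
  for (j in seq_len(config$n_goc)) {
    for (i in seq_len(config$n_mf)) {
      syn[[length(syn) + 1L]] <- prep_synapse(
        "mf_goc", 0L, i - 1L, j, "dend1", rel$mf_goc,
        list(rc("ampa", 1200 * mf_goc_scale),
             rc("nmda", 18800 * mf_goc_scale)),
        glu_trans, dt, FALSE)
    }
  }
  # GrC -> GoC feedback: parallel fiber (apical) and ascending axon
  for (j in seq_len(config$n_goc)) {
    syn[[length(syn) + 1L]] <- prep_synapse(
      "pf_goc", 1L, 0L, j, "dend2", rel$pf_goc,
      list(rc("ampa", 1200), rc("nmda", 18800), rc("kainate", 600)),
      glu_trans, dt, FALSE)
    syn[[length(syn) + 1L]] <- prep_synapse(
      "aa_goc", 1L, 0L, j, "dend3", rel$aa_goc,
      list(rc("ampa", 2400), rc("nmda", 37600)),
      glu_trans, dt, FALSE)
  }
  # GoC -> GrC inhibition: every Golgi cell contacts all four dendritic
  # glomeruli (single-GoC inhibition is intense); conductance per contact
  for (j in seq_len(config$n_goc)) {
    for (tip in tips) {
      syn[[length(syn) + 1L]] <- prep_synapse(
        "goc_grc", 1L, j, 0L, tip, rel$goc_grc,
        list(rc("gabaa_fast", 2500), rc("gabaa_slow", 600)),
        gaba_trans, dt, FALSE)
    }
  }
  # resolve compartment names to 0-based indices per postsynaptic cell
  syn <- lapply(syn, function(s) {
    s$post_comp <- match(s$post_comp,
                         cells[[s$post_cell + 1L]]$comps$name) - 1L
    s
  })
  structure(list(config = config, cells = cells, synapses = syn,
                 dt = dt, release = rel,
                 mf_goc_scale = if (config$n_goc > 0) mf_goc_scale else NA),
            class = "circuit")
}

#' @exportS3Method base::print
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit: %d mf, %d GoC, %d synapses, dt = %g ms>\n",
              x$config$n_mf, x$config$n_goc, length(x$synapses), x$dt))
  invisible(x)
}

# Low-level runner: flattens cells and dispatches to the C++ core.
circuit_run <- function(circuit, mf_times, t_stop, bias_grc = 0,
                        clamp = NULL, record_every = 1L,
                        release_log = FALSE) {
  cells <- circuit$cells
  flat <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cl <- if (!is.null(clamp) && clamp$cell == k)
      flatten_cell(cells[[k]], clamp_comp = "soma", clamp_v = clamp$v,
                   bias = 0)
    else flatten_cell(cells[[k]],
                      bias = if (k == 1L) bias_grc else 0)
    flat[[k]] <- cl
  }
  syn <- lapply(circuit$synapses, function(s) s)
  sim_run_cpp(flat, syn, lapply(mf_times, as.numeric), circuit$dt,
              t_stop, as.integer(record_every), 1.0, release_log)
}

#' Solve the granule-cell holding current for a circuit
#'
#' Finds the constant somatic injection holding the granule cell at
#' `v_target` (default -65 mV) in the quiescent circuit (no mossy-fiber
#' stimulation; Golgi pacemaking active).
#'
#' @param circuit a [wire_circuit()] result.
#' @param v_target target pre-stimulus potential (mV).
#' @param settle probe simulation length (ms).
#' @param tol tolerance (mV); default 0.4.
#' @return Bias current (nA).
#' @export
solve_circuit_bias <- function(circuit, v_target = -65, settle = 600,
                               tol = 0.25) {
  probe <- function(b) {
    out <- circuit_run(circuit, list(), settle, bias_grc = b,
                       record_every = 10L)
    stats::median(out$v[out$time > settle / 3, 1])
  }
  b0 <- 0; v0 <- probe(b0)
  if (abs(v0 - v_target) < tol) return(b0)
  b1 <- b0 + (v_target - v0) * 0.0012
  v1 <- probe(b1)
  for (i in 1:10) {
    if (abs(v1 - v_target) < tol) return(b1)
    if (abs(v1 - v0) < 1e-9) break
    b2 <- b1 + (v_target - v1) * (b1 - b0) / (v1 - v0)
    b0 <- b1; v0 <- v1; b1 <- b2; v1 <- probe(b2)
  }
  if (abs(v1 - v_target) > 1)
    stop(sprintf("bias solve failed: %.2f mV for target %.2f", v1, v_target))
  b1
}

#' Run a burst protocol in current clamp
#'
#' Delivers `n_pulses` mossy-fiber stimuli at the protocol frequency to
#' every mossy fiber, recording the granule-cell somatic voltage over
#' independent trials. The pre-stimulus potential is set to -65 mV (+/-
#' 0.5) by an automatically solved constant current. Stochastic release
#' is re-drawn per trial from a trial-indexed seed stream.
#'
#' @param circuit a [wire_circuit()] result.
#' @param protocol a [burst_protocol()].
#' @param stim_start time of the first pulse (ms); default 300, long
#'   enough for Golgi pacemaking and the sustained (slow GABA-A)
#'   component of inhibition to reach steady state.
#' @param post_window recording time after the last pulse (ms).
#' @param seed base seed; default the circuit configuration's.
#' @param record_every record every k-th step (default 4, i.e. 0.1 ms).
#' @param v_target pre-stimulus holding potential (mV).
#' @return A voltage [trace_set()].
#' @export
run_burst <- function(circuit, protocol, stim_start = 300,
                      post_window = 100, seed = NULL, record_every = 4L,
                      v_target = -65) {
  stopifnot(inherits(circuit, "circuit"),
            inherits(protocol, "burst_protocol"))
  seed <- seed %||% circuit$config$seed
  stim <- stim_start +
    (seq_len(protocol$n_pulses) - 1L) * 1000 / protocol$frequency
  t_stop <- max(stim) + post_window
  bias <- solve_circuit_bias(circuit, v_target = v_target)
  mf_times <- rep(list(stim), circuit$config$n_mf)
  traces <- NULL
  for (trial in seq_len(protocol$n_trials)) {
    set.seed(seed + (trial - 1L))
    out <- circuit_run(circuit, mf_times, t_stop, bias_grc = bias,
                       record_every = record_every)
    if (is.null(traces))
      traces <- matrix(NA_real_, nrow(out$v), protocol$n_trials)
    traces[, trial] <- out$v[, 1]
    time <- out$time
  }
  trace_set(time, traces, "voltage", stim_times = stim,
            protocol = c(unclass(protocol),
                         list(bias_nA = bias, v_target = v_target)),
            seed = seed)
}

#' Run a voltage-clamp protocol
#'
#' Clamps the soma of the chosen cell and records the clamp current while
#' mossy fibers are stimulated at the given times.
#'
#' @param circuit a [wire_circuit()] result.
#' @param v_hold holding potential (mV); default -70.
#' @param stim_times mossy-fiber stimulus times (ms).
#' @param t_stop simulation length (ms); default 100 past the last
#'   stimulus (or 100 ms if unstimulated).
#' @param cell index of the clamped cell (1 = granule cell).
#' @param n_trials independent trials.
#' @param seed base seed.
#' @param record_every record every k-th step.
#' @return A current [trace_set()] (pA; inward negative).
#' @export
run_voltage_clamp <- function(circuit, v_hold = -70,
                              stim_times = numeric(0), t_stop = NULL,
                              cell = 1L, n_trials = 1L, seed = NULL,
                              record_every = 4L) {
  stopifnot(inherits(circuit, "circuit"))
  seed <- seed %||% circuit$config$seed
  t_stop <- t_stop %||% (if (length(stim_times)) max(stim_times) + 100
                         else 100)
  mf_times <- rep(list(stim_times), circuit$config$n_mf)
  traces <- NULL
  for (trial in seq_len(n_trials)) {
    set.seed(seed + (trial - 1L))
    out <- circuit_run(circuit, mf_times, t_stop,
                       clamp = list(cell = cell, v = v_hold),
                       record_every = record_every)
    if (is.null(traces))
      traces <- matrix(NA_real_, nrow(out$i_clamp), n_trials)
    traces[, trial] <- out$i_clamp[, cell] * 1000  # nA -> pA
    time <- out$time
  }
  trace_set(time, traces, "current", stim_times = stim_times,
            protocol = list(v_hold = v_hold, cell = cell), seed = seed)
}

#' Run a theta-burst stimulation protocol
#'
#' Delivers the TBS schedule (default 10 pulses at 100 Hz, 8 bursts every
#' 250 ms, 80 stimuli) to the mossy fibers and records the granule-cell
#' response. TBS here verifies protocol timing and responses; it does not
#' itself induce plasticity (induction modeling is out of scope --
#' expression is applied through the plasticity configuration).
#'
#' @param circuit a [wire_circuit()] result.
#' @param protocol a [tbs_protocol()].
#' @param stim_start first-pulse time (ms).
#' @param seed RNG seed.
#' @param record_every record every k-th step.
#' @return A list with `stim_times` (the event log) and `traces`
#'   (a voltage [trace_set()], single trial).
#' @export
run_tbs <- function(circuit, protocol = tbs_protocol(), stim_start = 100,
                    seed = NULL, record_every = 8L) {
  stopifnot(inherits(circuit, "circuit"))
  seed <- seed %||% circuit$config$seed
  stim <- tbs_times(protocol, t0 = stim_start)
  bias <- solve_circuit_bias(circuit, v_target = -60)
  set.seed(seed)
  out <- circuit_run(circuit, rep(list(stim), circuit$config$n_mf),
                     max(stim) + 100, bias_grc = bias,
                     record_every = record_every)
  list(stim_times = stim,
       traces = trace_set(out$time, out$v[, 1, drop = FALSE], "voltage",
                          stim_times = stim,
                          protocol = unclass(protocol), seed = seed))
}

#' Single-stimulus mf-GoC EPSC in the isolated calibration setup
#'
#' Wires one mossy fiber onto the Golgi-cell model (AMPA + NMDA, mf-GrC
#' vesicle cycling, deterministic release), clamps the GoC soma at
#' -70 mV, delivers one stimulus and returns the baseline-subtracted peak
#' clamp current.
#'
#' @param config a [circuit_config()] (temperature and release-site count
#'   are used).
#' @param gmax_scale scale factor applied to the mf-GrC-derived AMPA and
#'   NMDA conductances.
#' @param dt integration step (ms).
#' @return Peak EPSC (pA, negative = inward).
#' @export
mf_goc_epsc_peak <- function(config, gmax_scale = 1, dt = 0.025) {
  schemes <- lapply(build_default_schemes(), adapt_scheme_temperature,
                    t_sim = config$temperature)
  fdiff <- 1 / q10_scale(1, 1.3, 37, config$temperature)
  rel <- synapse_classes(config$n_release_sites)
  glu <- transmitter_params(Ts_max = 0.6, Td_max = 0.18,
                            diff_tau = 1.2 * fdiff)
  goc <- build_goc()
  goc$temperature <- config$temperature
  syn <- prep_synapse("mf_goc", 0L, 0L, 0L, "dend1", rel$mf_goc,
                      list(prep_receptor(schemes$ampa,
                                         1200 * gmax_scale, dt),
                           prep_receptor(schemes$nmda,
                                         18800 * gmax_scale, dt)),
                      glu, dt, FALSE)
  syn$post_comp <- match("dend1", goc$comps$name) - 1L
  fc <- flatten_cell(goc, clamp_comp = "soma", clamp_v = -70, bias = 0)
  out <- sim_run_cpp(list(fc), list(syn), list(20), dt, 80, 1L, 1.0,
                     FALSE)
  i <- out$i_clamp[, 1] * 1000
  base <- stats::median(i[out$time < 20])
  min(i[out$time >= 20]) - base          # negative (inward)
}

# Calibrate the mf-GoC conductance scale reproducing a -66 pA peak EPSC
# for a single deterministic stimulus with the GoC soma clamped at -70 mV.
calibrate_mf_goc_scale <- function(config, dt = 0.025) {
  p1 <- -mf_goc_epsc_peak(config, 1, dt)
  scale <- 66 / p1
  # one correction step for the mild NMDA/driving-force nonlinearity
  p2 <- -mf_goc_epsc_peak(config, scale, dt)
  scale * 66 / p2
}
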