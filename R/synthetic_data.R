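#' Synthetic patch-clamp data configuration
#'
#' Generator settings with the statistical structure the analysis
#' pipelines assume. Defaults follow the experimental means: EPSC
#' amplitude 29.7 pA, EPSP 11.4 mV, paired-pulse ratio 0.78, and the
#' population compound-gain sigmoid (A1 = 1.03, A2 = 2.69,
#' fc = 43.2 Hz). Plasticity effect sizes default to the measured
#' population changes: LTP +28.5% EPSC / +31.2% EPSP / -27.4% PPR, LTD
#' -36.8% / -27.8% / +23.8%.
#'
#' @param seed base RNG seed.
#' @param noise_current_pA additive white noise SD on currents.
#' @param noise_voltage_mV additive white noise SD on voltages.
#' @param epsc_rise_ms,epsc_decay_ms double-exponential EPSC shape.
#' @param amplitude_pA mean EPSC amplitude (reported as magnitude; the
#'   generated deflections are inward/negative).
#' @param amplitude_cv trial-to-trial amplitude coefficient of variation.
#' @param epsp_mV mean single-stimulus EPSP amplitude.
#' @param ppr paired-pulse ratio of the generator.
#' @param sp_profile per-pulse spike-probability sigmoid parameters
#'   (A1, A2, fc, power), clamped to \[0, 1\].
#' @param amd_profile depolarization sigmoid parameters (mV).
#' @param latency_ms mean spike latency after a pulse.
#' @param jitter_ms first-spike latency SD.
#' @param effects plasticity effect sizes (percent), entries `ltp` and
#'   `ltd` with `epsc`, `epsp`, `ppr`, `fc`, `gain`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         noise_current_pA = 2, noise_voltage_mV = 0.5,
                         epsc_rise_ms = 0.3, epsc_decay_ms = 3,
                         amplitude_pA = 29.7, amplitude_cv = 0.05,
                         epsp_mV = 11.4, ppr = 0.78,
                         sp_profile = c(A1 = 0.02, A2 = 0.9, fc = 43.2,
                                        power = 4),
                         amd_profile = c(A1 = 4, A2 = 12, fc = 43.2,
                                         power = 4),
                         latency_ms = 3, jitter_ms = 1,
                         effects = list(
                           ltp = c(epsc = 28.5, epsp = 31.2, ppr = -27.4,
                                   fc = -40, gain = 24),
                           ltd = c(epsc = -36.8, epsp = -27.8, ppr = 23.8,
                                   fc = 50, gain = -13))) {
  stopifnot(noise_current_pA >= 0, noise_voltage_mV >= 0,
            epsc_rise_ms > 0, epsc_decay_ms > epsc_rise_ms,
            amplitude_pA > 0, ppr > 0)
  structure(list(seed = as.integer(seed),
                 noise_current_pA = noise_current_pA,
                 noise_voltage_mV = noise_voltage_mV,
                 epsc_rise_ms = epsc_rise_ms,
                 epsc_decay_ms = epsc_decay_ms,
                 amplitude_pA = amplitude_pA,
                 amplitude_cv = amplitude_cv,
                 epsp_mV = epsp_mV, ppr = ppr,
                 sp_profile = sp_profile, amd_profile = amd_profile,
                 latency_ms = latency_ms, jitter_ms = jitter_ms,
                 effects = effects),
            class = "synth_config")
}

#' Synthetic voltage-clamp step transient
#'
#' Analytic response of the series-resistance/membrane RC circuit to a
#' voltage step: I(t) = (dV/Rs) exp(-t/tau) + dV/(Rs + Rm) with
#' tau = Cm Rs Rm/(Rs + Rm), sampled at 20 kHz, plus Gaussian noise
#' scaled to the peak.
#'
#' @param Cm_pF membrane capacitance (pF).
#' @param Rm_GOhm membrane resistance (GOhm).
#' @param Rs_MOhm series resistance (MOhm).
#' @param dV_mV step amplitude (mV); default the standard 10 mV step.
#' @param duration_ms trace length (ms).
#' @param fs_Hz sampling rate; default 20 kHz.
#' @param noise_frac noise SD as a fraction of the peak current.
#' @param seed RNG seed.
#' @return List with `time` (ms), `current` (pA), and `truth`
#'   (tau_ms, I_peak, I_ss).
#' @export
gen_vc_transient <- function(Cm_pF = 2.4, Rm_GOhm = 2.3, Rs_MOhm = 17.5,
                             dV_mV = 10, duration_ms = 500,
                             fs_Hz = 20000, noise_frac = 0.02,
                             seed = NULL) {
  stopifnot(Cm_pF > 0, Rm_GOhm > 0, Rs_MOhm > 0)
  if (!is.null(seed)) set.seed(seed)
  Rs_G <- Rs_MOhm / 1000
  tau_ms <- Cm_pF * Rs_G * Rm_GOhm / (Rs_G + Rm_GOhm)
  time <- seq(0, duration_ms, by = 1000 / fs_Hz)
  ipk <- dV_mV / Rs_G
  iss <- dV_mV / (Rs_G + Rm_GOhm)
  i <- (ipk - iss) * exp(-time / tau_ms) + iss
  i <- i + stats::rnorm(length(i), 0, noise_frac * ipk)
  list(time = time, current = i,
       truth = c(tau_ms = tau_ms, I_peak = ipk, I_ss = iss))
}

epsc_kernel <- function(t, rise, decay) {
  k <- exp(-t / decay) - exp(-t / rise)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  k / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Synthetic EPSC train
#'
#' Sum of double-exponential inward EPSCs at the stimulus times, each
#' scaled by the per-stimulus `ppr_profile` (e.g. c(1, 0.78) for a
#' paired pulse at the control paired-pulse ratio) and by a
#' trial-amplitude drawn with the configured coefficient of variation;
#' Gaussian current noise added.
#'
#' @param stim_times sorted stimulus times (ms).
#' @param config a [synth_config()].
#' @param ppr_profile per-stimulus amplitude scaling; default
#'   c(1, ppr) for two stimuli, else all 1.
#' @param n_trials trials.
#' @param duration_ms trace length; default last stimulus + 50.
#' @param fs_Hz sampling rate.
#' @param seed RNG seed; default the configuration's.
#' @return A current [trace_set()] (pA; EPSCs negative).
#' @export
gen_epsc_train <- function(stim_times, config = synth_config(),
                           ppr_profile = NULL, n_trials = 1L,
                           duration_ms = NULL, fs_Hz = 20000,
                           seed = NULL) {
  stopifnot(length(stim_times) >= 1, !is.unsorted(stim_times))
  set.seed(seed %||% config$seed)
  if (is.null(ppr_profile))
    ppr_profile <- if (length(stim_times) == 2L) c(1, config$ppr)
                   else rep(1, length(stim_times))
  stopifnot(length(ppr_profile) == length(stim_times))
  duration_ms <- duration_ms %||% (max(stim_times) + 50)
  time <- seq(0, duration_ms, by = 1000 / fs_Hz)
  tr <- matrix(0, length(time), n_trials)
  for (j in seq_len(n_trials)) {
    amp <- config$amplitude_pA *
      max(stats::rnorm(1, 1, config$amplitude_cv), 0.05)
    v <- numeric(length(time))
    for (k in seq_along(stim_times)) {
      on <- time >= stim_times[k]
      v[on] <- v[on] - amp * ppr_profile[k] *
        epsc_kernel(time[on] - stim_times[k],
                    config$epsc_rise_ms, config$epsc_decay_ms)
    }
    tr[, j] <- v + stats::rnorm(length(time), 0, config$noise_current_pA)
  }
  trace_set(time, tr, "current", stim_times = stim_times,
            protocol = list(generator = "gen_epsc_train"),
            seed = seed %||% config$seed)
}

spike_waveform <- function(t, peak_mV = 30, base_mV) {
  # 1 ms triangular surrogate; only threshold crossings matter downstream
  w <- numeric(length(t))
  up <- t >= 0 & t < 0.5
  dn <- t >= 0.5 & t < 1
  w[up] <- (peak_mV - base_mV) * (t[up] / 0.5)
  w[dn] <- (peak_mV - base_mV) * (1 - (t[dn] - 0.5) / 0.5)
  w
}

#' Synthetic burst voltage responses at one frequency
#'
#' Emulates current-clamp responses to a five-pulse mossy-fiber burst:
#' an EPSP staircase whose peak depolarization follows the configured
#' sigmoid profile of frequency; a spike burst emitted with the
#' configured sigmoidal probability (the first suprathreshold pulse
#' always spikes in a spiking trial, later pulses spike with the
#' normalized drive probability, so the spike count also grows along the
#' profile); first-spike latency jitter that tightens as the drive grows
#' (high-frequency bursts are more precise); a stereotyped 1 ms spike
#' waveform superimposed; and Gaussian voltage noise.
#'
#' @param frequency burst frequency (Hz).
#' @param config a [synth_config()].
#' @param n_trials trials; default 10.
#' @param n_pulses pulses per burst; default 5.
#' @param baseline_mV resting/holding potential; default -65.
#' @param fs_Hz sampling rate; default 10 kHz.
#' @param seed RNG seed; default the configuration's.
#' @return A voltage [trace_set()] with `protocol$frequency` set.
#' @export
gen_burst_responses <- function(frequency, config = synth_config(),
                                n_trials = 10L, n_pulses = 5L,
                                baseline_mV = -65, fs_Hz = 10000,
                                seed = NULL) {
  stopifnot(frequency > 0)
  set.seed(seed %||% config$seed)
  isi <- 1000 / frequency
  stim <- 50 + (seq_len(n_pulses) - 1L) * isi
  t_stop <- max(stim) + 80
  time <- seq(0, t_stop, by = 1000 / fs_Hz)
  sp <- config$sp_profile
  q <- gain_sigmoid(frequency, sp[["A1"]], sp[["A2"]], sp[["fc"]],
                    sp[["power"]])
  q <- min(max(q, 0), 1)
  # normalized drive along the profile, in [0, 1]
  drive <- if (abs(sp[["A2"]] - sp[["A1"]]) < 1e-12) {
    as.numeric(q > 0.5)
  } else {
    min(max((q - sp[["A1"]]) / (sp[["A2"]] - sp[["A1"]]), 0), 1)
  }
  jitter <- config$jitter_ms * (1 - 0.8 * drive)
  am <- config$amd_profile
  amd_target <- gain_sigmoid(frequency, am[["A1"]], am[["A2"]],
                             am[["fc"]], am[["power"]])
  tr <- matrix(0, length(time), n_trials)
  # EPSP staircase: per-pulse alpha-like EPSPs whose summed peak reaches
  # the target depolarization
  tau_r <- 2; tau_d <- max(12, isi * 0.8)
  shape <- function(t) ifelse(t < 0, 0, exp(-t / tau_d) - exp(-t / tau_r))
  stair <- rowSums(sapply(stim, function(s) shape(time - s)))
  stair <- stair / max(stair) * amd_target
  for (j in seq_len(n_trials)) {
    v <- baseline_mV + stair
    spikes <- numeric(0)
    if (stats::runif(1) < q) {
      fire <- c(TRUE, stats::runif(n_pulses - 1) < drive)
      for (k in which(fire)) {
        lat <- config$latency_ms + stats::rnorm(1, 0, jitter)
        spikes <- c(spikes, stim[k] + max(lat, 0.2))
      }
    }
    for (s in spikes)
      v <- v + spike_waveform(time - s, 30, baseline_mV)
    tr[, j] <- v + stats::rnorm(length(time), 0, config$noise_voltage_mV)
  }
  trace_set(time, tr, "voltage", stim_times = stim,
            protocol = list(frequency = frequency,
                            generator = "gen_burst_responses"),
            seed = seed %||% config$seed)
}

#' Apply a long-term plasticity effect to the generator configuration
#'
#' Scales the EPSC/EPSP amplitudes and the paired-pulse ratio by the
#' configured effect sizes and shifts the gain profiles (cutoff down and
#' amplitudes up for LTP; the converse for LTD).
#'
#' @param config a [synth_config()].
#' @param mode `"control"`, `"ltp"` or `"ltd"`.
#' @return The updated configuration.
#' @export
apply_plasticity_effect <- function(config, mode) {
  mode <- match.arg(tolower(mode), c("control", "ltp", "ltd"))
  if (mode == "control") return(config)
  e <- config$effects[[mode]]
  config$amplitude_pA <- config$amplitude_pA * (1 + e[["epsc"]] / 100)
  config$epsp_mV <- config$epsp_mV * (1 + e[["epsp"]] / 100)
  config$ppr <- config$ppr * (1 + e[["ppr"]] / 100)
  for (pf in c("sp_profile", "amd_profile")) {
    config[[pf]][["fc"]] <- config[[pf]][["fc"]] * (1 + e[["fc"]] / 100)
    config[[pf]][["A1"]] <- config[[pf]][["A1"]] * (1 + e[["gain"]] / 100)
    config[[pf]][["A2"]] <- config[[pf]][["A2"]] * (1 + e[["gain"]] / 100)
  }
  config
}

#' Synthetic noisy gain curves from the sigmoidal gain function
#'
#' Evaluates [gain_sigmoid()] at the given frequencies and adds i.i.d.
#' Gaussian noise per replicate.
#'
#' @param A1,A2,fc,power sigmoid parameters.
#' @param freqs frequencies (Hz).
#' @param noise_sd Gaussian noise SD.
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @return List with `freqs`, `gain` (matrix reps x freqs) and `truth`.
#' @export
gen_gain_curve <- function(A1, A2, fc, power, freqs, noise_sd = 0.1,
                           n_reps = 1L, seed = NULL) {
  stopifnot(fc > 0, power > 0, all(freqs > 0))
  if (!is.null(seed)) set.seed(seed)
  mu <- gain_sigmoid(freqs, A1, A2, fc, power)
  g <- matrix(rep(mu, each = n_reps), n_reps, length(freqs)) +
    stats::rnorm(n_reps * length(freqs), 0, noise_sd)
  list(freqs = freqs, gain = g,
       truth = c(A1 = A1, A2 = A2, fc = fc, power = power))
}
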