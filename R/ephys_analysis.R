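#' Fit passive membrane parameters from a voltage-clamp transient
#'
#' Fits the monoexponential relaxation I(t) = I_ss + (I_peak - I_ss) *
#' exp(-t/tau) evoked by a voltage step `dV` (the standard protocol uses a
#' 10 mV step from -70 mV), then recovers the series resistance
#' Rs = dV/I_peak, the membrane resistance Rm = dV/I_ss - Rs and the
#' membrane capacitance Cm = tau (Rs + Rm)/(Rs Rm).
#'
#' @param time time base (ms), starting at the step onset.
#' @param current clamp current (pA).
#' @param dV step amplitude (mV); must be nonzero.
#' @return An object of class `passive_params`: `Cm_pF`, `Rm_GOhm`,
#'   `Rs_MOhm`, `tau_us`, `fit_residual` (RMS, pA).
#' @export
fit_passive <- function(time, current, dV) {
  if (!is.numeric(dV) || length(dV) != 1L || dV == 0)
    stop("'dV' must be a single nonzero voltage step (mV)")
  stopifnot(length(time) == length(current), length(time) > 4)
  t <- time - time[1]
  iss0 <- mean(current[t >= 0.75 * max(t)])
  a0 <- current[1] - iss0
  if (abs(a0) < 4 * stats::sd(current[t >= 0.75 * max(t)])) {
    warning("no resolvable transient: pure-resistor limit (tau -> 0)")
    Rs <- NA_real_
    Rm <- dV / iss0
    return(structure(list(Cm_pF = 0, Rm_GOhm = Rm, Rs_MOhm = NA_real_,
                          tau_us = 0, fit_residual = NA_real_),
                     class = "passive_params"))
  }
  # log-linear initialization on the early decay
  early <- which((current - iss0) / a0 > 0.1 & t < 0.5 * max(t))
  tau0 <- tryCatch({
    y <- log((current[early] - iss0) / a0)
    -1 / stats::coef(stats::lm(y ~ t[early]))[[2]]
  }, error = function(e) NA_real_)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 20
  df <- data.frame(t = t, i = current)
  fit <- tryCatch(
    minpack.lm::nlsLM(i ~ iss + a * exp(-t / tau), data = df,
                      start = list(iss = iss0, a = a0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("passive fit failed to converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  ipk <- cf[["iss"]] + cf[["a"]]
  Rs_G <- dV / ipk                        # mV/pA = GOhm
  Rm_G <- dV / cf[["iss"]] - Rs_G
  tau_ms <- cf[["tau"]]
  Cm_pF <- tau_ms * (Rs_G + Rm_G) / (Rs_G * Rm_G)  # ms/GOhm = pF
  structure(list(Cm_pF = Cm_pF, Rm_GOhm = Rm_G, Rs_MOhm = Rs_G * 1000,
                 tau_us = tau_ms * 1000,
                 fit_residual = sqrt(mean(stats::resid(fit)^2))),
            class = "passive_params")
}

#' @exportS3Method base::print
print.passive_params <- function(x, ...) {
  cat(sprintf("<passive fit: Cm = %.3g pF, Rm = %.3g GOhm, Rs = %.3g MOhm, tau = %.3g us>\n",
              x$Cm_pF, x$Rm_GOhm, x$Rs_MOhm, x$tau_us))
  invisible(x)
}

boxcar <- function(x, w) {
  if (w <= 1L) return(x)
  stats::filter(x, rep(1 / w, w), sides = 2) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; as.numeric(y) })()
}

#' EPSC peak amplitudes after each stimulus
#'
#' Baseline-subtracted extremum in a post-stimulus window. The extremum
#' is located on a lightly boxcar-smoothed copy of the trace (robust to
#' noise), but the amplitude is measured on the raw trace averaged over
#' a narrow window around that location, which keeps the estimate
#' unbiased under additive noise. The baseline is the mean over the 5 ms
#' preceding each stimulus. Amplitudes are reported as magnitudes
#' (inward currents are negative deflections).
#'
#' @param trace a current [trace_set()], or a list with `time` and
#'   `traces` (vector or matrix).
#' @param stim_times stimulus times (ms), inside the trace.
#' @param window peak search window after each stimulus (ms); default 10.
#' @param baseline_ms pre-stimulus baseline window (ms); default 5.
#' @param smooth_ms boxcar width for the extremum search (ms).
#' @param measure_ms half-width of the raw-trace averaging window around
#'   the located extremum (ms).
#' @return Matrix of amplitudes (pA), stimuli x trials.
#' @export
epsc_peaks <- function(trace, stim_times, window = 10, baseline_ms = 5,
                       smooth_ms = 0.5, measure_ms = 0.1) {
  time <- trace$time
  tr <- as.matrix(trace$traces)
  stopifnot(length(stim_times) >= 1,
            all(stim_times >= time[1] & stim_times <= max(time)))
  if (length(stim_times) > 1 && any(diff(stim_times) < window))
    stop("peak search windows overlap; reduce 'window'")
  dt <- time[2] - time[1]
  w <- max(1L, round(smooth_ms / dt))
  out <- matrix(NA_real_, length(stim_times), ncol(tr))
  for (j in seq_len(ncol(tr))) {
    sm <- boxcar(tr[, j], w)
    for (k in seq_along(stim_times)) {
      s <- stim_times[k]
      base <- mean(tr[time >= s - baseline_ms & time < s, j])
      idx <- which(time > s & time <= s + window)
      pk <- idx[which.max(abs(sm[idx] - base))]
      near <- abs(time - time[pk]) <= measure_ms + dt / 2
      out[k, j] <- abs(mean(tr[near, j]) - base)
    }
  }
  out
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first evoked EPSC peak (two stimuli,
#' canonically 20 ms apart); values below 1 indicate paired-pulse
#' depression, above 1 facilitation.
#'
#' @param trace a current [trace_set()] or list with `time`, `traces`.
#' @param stim_times exactly two stimulus times (ms).
#' @param ... passed to [epsc_peaks()].
#' @return Numeric vector, one ratio per trial.
#' @export
ppr <- function(trace, stim_times, ...) {
  if (length(stim_times) != 2L)
    stop("paired-pulse ratio needs exactly two stimuli")
  pk <- epsc_peaks(trace, stim_times, ...)
  if (any(pk[1, ] == 0)) stop("first EPSC peak is zero")
  pk[2, ] / pk[1, ]
}

#' Percent change between pre and post response amplitudes
#'
#' 100 * (mean(post) - mean(pre)) / mean(pre). When `pre` and `post` are
#' paired (equal length), the per-pair percent changes and their standard
#' error are also returned.
#'
#' @param pre pre-induction amplitudes.
#' @param post post-induction amplitudes.
#' @return List with `change` (percent), and for paired inputs
#'   `per_cell` and `sem`.
#' @export
percent_change <- function(pre, post) {
  if (!length(pre) || !length(post)) stop("empty input")
  if (mean(pre) == 0) stop("pre mean is zero")
  change <- 100 * (mean(post) - mean(pre)) / mean(pre)
  out <- list(change = change, per_cell = NULL, sem = NA_real_)
  if (length(pre) == length(post) && length(pre) > 1) {
    pc <- 100 * (post - pre) / pre
    out$per_cell <- pc
    out$sem <- stats::sd(pc) / sqrt(length(pc))
  }
  out
}

#' Classify a plasticity outcome from the EPSC percent change
#'
#' LTP above +`dead_band` percent, LTD below -`dead_band`, otherwise
#' none. The dead band guards borderline synthetic cases.
#'
#' @param epsc_change percent change of the EPSC amplitude.
#' @param dead_band half-width of the no-change band (percent).
#' @return `"ltp"`, `"ltd"` or `"none"`.
#' @export
classify_plasticity <- function(epsc_change, dead_band = 5) {
  if (epsc_change > dead_band) "ltp"
  else if (epsc_change < -dead_band) "ltd"
  else "none"
}

#' Summarize a pre/post plasticity experiment
#'
#' @param pre_epsc,post_epsc EPSC amplitudes (pA) before/after induction.
#' @param pre_ppr,post_ppr paired-pulse ratios before/after (optional).
#' @param pre_epsp,post_epsp EPSP amplitudes (mV) before/after (optional).
#' @return An object of class `plasticity_outcome`: percent changes, the
#'   PPR pair and the classification.
#' @export
plasticity_outcome <- function(pre_epsc, post_epsc,
                               pre_ppr = NULL, post_ppr = NULL,
                               pre_epsp = NULL, post_epsp = NULL) {
  ec <- percent_change(pre_epsc, post_epsc)
  pc <- if (!is.null(pre_epsp)) percent_change(pre_epsp, post_epsp)
        else list(change = NA_real_)
  rc <- if (!is.null(pre_ppr)) percent_change(pre_ppr, post_ppr)
        else list(change = NA_real_)
  structure(list(epsc_change = ec$change, epsc_sem = ec$sem,
                 epsp_change = pc$change,
                 ppr_pre = if (is.null(pre_ppr)) NA_real_
                           else mean(pre_ppr),
                 ppr_post = if (is.null(post_ppr)) NA_real_
                            else mean(post_ppr),
                 ppr_change = rc$change,
                 classification = classify_plasticity(ec$change)),
            class = "plasticity_outcome")
}

#' @exportS3Method base::print
print.plasticity_outcome <- function(x, ...) {
  cat(sprintf("<plasticity: EPSC %+.1f%%, PPR %.2f -> %.2f, class %s>\n",
              x$epsc_change, x$ppr_pre, x$ppr_post,
              toupper(x$classification)))
  invisible(x)
}
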