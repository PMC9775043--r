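#' Detect spikes as threshold crossings
#'
#' Upward crossings of the voltage threshold (default -20 mV) with a
#' refractory de-duplication window.
#'
#' @param time uniform time base (ms).
#' @param v voltage trace (mV).
#' @param threshold crossing threshold (mV).
#' @param refractory minimum separation between events (ms).
#' @return Spike times (ms).
#' @export
detect_spikes <- function(time, v, threshold = -20, refractory = 1) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  tt <- time[up]
  keep <- c(TRUE, diff(tt) > refractory)
  while (any(!keep)) {
    tt <- tt[keep]
    keep <- c(TRUE, diff(tt) > refractory)
  }
  tt
}

#' Per-frequency burst response metrics
#'
#' From a repeated-trial voltage response to a stimulus burst, measures
#' the four gain parameters: `sc` (mean spike count per trial), `sp`
#' (probability of emitting at least one spike in the burst), `fssd`
#' (standard deviation of the first-spike latency across spiking trials,
#' n-1 denominator; undefined with fewer than two spiking trials) and
#' `amd` (average maximum depolarization relative to the pre-stimulus
#' baseline). The analysis window runs from the first stimulus to 50 ms
#' after the last one.
#'
#' @param traces a voltage [trace_set()] with at least 2 trials.
#' @param window analysis window c(start, end) (ms); default first
#'   stimulus to last + 50.
#' @param threshold spike threshold (mV).
#' @param baseline_ms pre-stimulus baseline length (ms).
#' @return An object of class `burst_metrics`.
#' @export
burst_metrics <- function(traces, window = NULL, threshold = -20,
                          baseline_ms = 20) {
  stopifnot(inherits(traces, "trace_set"),
            traces$modality == "voltage",
            ncol(traces$traces) >= 2)
  stim <- traces$stim_times
  if (is.null(window)) {
    if (!length(stim)) stop("no stimulus times and no explicit window")
    window <- c(min(stim), max(stim) + 50)
  }
  if (diff(window) <= 0) stop("empty analysis window")
  time <- traces$time
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("empty analysis window")
  nt <- ncol(traces$traces)
  counts <- integer(nt); first <- rep(NA_real_, nt); amd_i <- numeric(nt)
  for (j in seq_len(nt)) {
    v <- traces$traces[, j]
    spk <- detect_spikes(time, v, threshold)
    spk <- spk[spk >= window[1] & spk <= window[2]]
    counts[j] <- length(spk)
    if (length(spk)) first[j] <- spk[1] - window[1]
    base <- mean(v[time >= window[1] - baseline_ms & time < window[1]])
    amd_i[j] <- max(v[sel]) - base
  }
  spiking <- which(counts > 0)
  structure(list(
    frequency = traces$protocol$frequency %||% NA_real_,
    sc = mean(counts),
    sp = mean(counts > 0),
    fssd = if (length(spiking) >= 2) stats::sd(first[spiking])
           else NA_real_,
    amd = mean(amd_i),
    n_trials = nt), class = "burst_metrics")
}

#' Gain curve container
#'
#' @param frequencies strictly increasing frequencies (Hz).
#' @param gain gain values (compound index in \[0, 4\] or normalized amd
#'   in \[0, 1\]).
#' @param kind `"cGI"` or `"amd"`.
#' @param components optional data.frame of the normalized components.
#' @return An object of class `gain_curve`.
#' @export
gain_curve <- function(frequencies, gain, kind = c("cGI", "amd"),
                       components = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(frequencies) == length(gain),
            all(diff(frequencies) > 0))
  structure(list(frequencies = frequencies, gain = gain, kind = kind,
                 components = components), class = "gain_curve")
}

minmax01 <- function(x) {
  if (all(is.na(x))) return(rep(0, length(x)))
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Compound gain index across frequencies
#'
#' Rescales each burst metric to \[0, 1\] across this cell's tested
#' frequencies (min-max), inverting the first-spike jitter so 1
#' corresponds to minimum jitter, and sums the four normalized metrics
#' into the compound gain index cGI in \[0, 4\]. An undefined fssd (fewer
#' than two spiking trials) normalizes to 0 (worst case); an all-constant
#' metric contributes 0.
#'
#' @param metrics list of [burst_metrics()] (one per frequency) or a
#'   data.frame with columns `frequency`, `sc`, `sp`, `fssd`, `amd`.
#' @param reference optional metrics (same formats) whose per-metric
#'   extremes define the normalization instead of `metrics`' own; used
#'   when comparing conditions (e.g. plasticity states against control)
#'   on a common scale, where curves may then leave \[0, 4\].
#' @return A [gain_curve()] of kind `"cGI"` (components attached).
#' @export
normalize_and_compound <- function(metrics, reference = NULL) {
  as_df <- function(m) {
    if (is.data.frame(m)) m
    else do.call(rbind, lapply(m, function(x)
      data.frame(frequency = x$frequency, sc = x$sc, sp = x$sp,
                 fssd = x$fssd, amd = x$amd)))
  }
  df <- as_df(metrics)
  stopifnot(nrow(df) >= 3)
  df <- df[order(df$frequency), ]
  ref <- if (is.null(reference)) df else as_df(reference)
  scale01 <- function(x, r) {
    if (all(is.na(r))) return(rep(0, length(x)))
    rng <- range(r, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0, length(x)))
    (x - rng[1]) / diff(rng)
  }
  n_sc <- scale01(df$sc, ref$sc)
  n_sp <- scale01(df$sp, ref$sp)
  n_amd <- scale01(df$amd, ref$amd)
  n_fssd <- 1 - scale01(df$fssd, ref$fssd)
  # undefined jitter (fewer than two spiking trials) is the worst case
  n_fssd[is.na(df$fssd)] <- 0
  if (all(is.na(ref$fssd)) || diff(range(ref$fssd, na.rm = TRUE)) == 0)
    n_fssd[] <- 0
  comp <- data.frame(frequency = df$frequency, sc = n_sc, sp = n_sp,
                     fssd = n_fssd, amd = n_amd)
  gain_curve(df$frequency, n_sc + n_sp + n_fssd + n_amd, "cGI",
             components = comp)
}

#' Sigmoidal gain function
#'
#' g(f) = (A1 - A2)/(1 + (f/fc)^p) + A2: a Hill-like sigmoid in input
#' frequency running from A1 (low-frequency asymptote) to A2
#' (high-frequency asymptote) with midpoint (cutoff) fc; by construction
#' g(fc) = (A1 + A2)/2.
#'
#' @param f frequency (Hz).
#' @param A1,A2 low/high-frequency asymptotes.
#' @param fc cutoff frequency (Hz).
#' @param power Hill-like exponent.
#' @return Gain values.
#' @export
gain_sigmoid <- function(f, A1, A2, fc, power) {
  (A1 - A2) / (1 + (f / fc)^power) + A2
}

#' Fit the sigmoidal gain function to a gain curve
#'
#' Least-squares fit of [gain_sigmoid()] with a multi-start over a
#' cutoff-frequency grid; the exponent starts at 4 and is bounded in
#' \[0.5, 20\], fc is bounded within a decade of the tested range.
#'
#' @param curve a [gain_curve()], or a list/data.frame with
#'   `frequencies` and `gain`.
#' @param fc_grid multi-start cutoff grid (Hz).
#' @param power_init initial exponent.
#' @param power_bounds exponent bounds.
#' @param sigma optional known noise SD for the chi-square fit quality.
#' @return An object of class `sigmoid_fit`: `A1`, `A2`, `fc`, `power`,
#'   `rss`, `chisq_p` (NA without `sigma`).
#' @export
fit_gain_sigmoid <- function(curve, fc_grid = c(10, 30, 50, 100, 200),
                             power_init = 4, power_bounds = c(0.5, 20),
                             sigma = NULL) {
  f <- curve$frequencies
  g <- curve$gain
  stopifnot(length(f) >= 4, length(f) == length(g))
  df <- data.frame(f = f, g = g)
  lower <- c(A1 = -Inf, A2 = -Inf, fc = min(f) / 10, p = power_bounds[1])
  upper <- c(A1 = Inf, A2 = Inf, fc = max(f) * 10, p = power_bounds[2])
  best <- NULL
  for (fc0 in fc_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(g ~ (A1 - A2) / (1 + (f / fc)^p) + A2, data = df,
                        start = list(A1 = min(g) + 1e-6,
                                     A2 = max(g), fc = fc0,
                                     p = power_init),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from every start")
  cf <- stats::coef(best$fit)
  chisq_p <- if (!is.null(sigma)) {
    stats::pchisq(best$rss / sigma^2, df = length(f) - 4,
                  lower.tail = FALSE)
  } else NA_real_
  structure(list(A1 = cf[["A1"]], A2 = cf[["A2"]], fc = cf[["fc"]],
                 power = cf[["p"]], rss = best$rss, chisq_p = chisq_p,
                 n = length(f)), class = "sigmoid_fit")
}

#' @exportS3Method base::print
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid fit: A1 = %.3g, A2 = %.3g, fc = %.3g Hz, p = %.3g>\n",
              x$A1, x$A2, x$fc, x$power))
  invisible(x)
}

#' Pre/post comparison of fitted gain curves
#'
#' Percent changes of the cutoff frequency, of the maximum gain
#' (max(A1, A2)) and of the relative gain (Gmax - Gmin)/Gmin between two
#' sigmoid fits.
#'
#' @param fit_pre,fit_post [fit_gain_sigmoid()] results.
#' @return List with `dfc_pct`, `dmax_gain_pct`, `drelative_gain_pct`,
#'   plus the underlying values; relative gain is NA (flagged) when
#'   Gmin <= 0.
#' @export
gain_summary <- function(fit_pre, fit_post) {
  gmax <- function(f) max(f$A1, f$A2)
  gmin <- function(f) min(f$A1, f$A2)
  rel <- function(f) {
    if (gmin(f) <= 0) return(NA_real_)
    (gmax(f) - gmin(f)) / gmin(f)
  }
  r1 <- rel(fit_pre); r2 <- rel(fit_post)
  list(fc_pre = fit_pre$fc, fc_post = fit_post$fc,
       dfc_pct = 100 * (fit_post$fc - fit_pre$fc) / fit_pre$fc,
       max_gain_pre = gmax(fit_pre), max_gain_post = gmax(fit_post),
       dmax_gain_pct = 100 * (gmax(fit_post) - gmax(fit_pre)) /
         gmax(fit_pre),
       relative_gain_pre = r1, relative_gain_post = r2,
       drelative_gain_pct = if (is.na(r1) || is.na(r2) || r1 == 0)
         NA_real_ else 100 * (r2 - r1) / r1)
}

#' Histogram of cutoff frequencies across cells
#'
#' Left-closed, right-open bins (an fc on an edge counts in the bin to
#' its right), default edges 0, 20, 50, 100, 200, 500 Hz.
#'
#' @param fits list of [fit_gain_sigmoid()] results, or numeric fc
#'   values.
#' @param breaks bin edges (Hz).
#' @return data.frame with `bin` labels and `count`.
#' @export
cutoff_histogram <- function(fits, breaks = c(0, 20, 50, 100, 200, 500)) {
  fc <- if (is.numeric(fits)) fits
        else vapply(fits, function(f) f$fc, numeric(1))
  stopifnot(length(fc) >= 1)
  cuts <- cut(fc, breaks = breaks, right = FALSE)
  data.frame(bin = levels(cuts),
             count = as.integer(table(cuts)))
}
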