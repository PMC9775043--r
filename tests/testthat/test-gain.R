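test_that("detect_spikes finds crossings and merges doublets", {
  time <- seq(0, 100, by = 0.1)
  v <- rep(-70, length(time))
  expect_length(detect_spikes(time, v), 0L)
  insert <- function(v, at, width = 1) {
    idx <- which(time >= at & time < at + width)
    v[idx] <- 20; v
  }
  v3 <- insert(insert(insert(v, 10), 30), 55)
  got <- detect_spikes(time, v3)
  expect_length(got, 3L)
  expect_true(all(abs(got - c(10, 30, 55)) <= 0.2))
  # doublet 0.5 ms apart merges under the 1 ms refractory rule
  vd <- rep(-70, length(time))
  vd[time >= 10 & time < 10.2] <- 20
  vd[time >= 10.5 & time < 10.7] <- 20
  expect_length(detect_spikes(time, vd), 1L)
})

mk_traces <- function(latencies, n_silent = 0, baseline = -65,
                      window_start = 50) {
  time <- seq(0, 150, by = 0.1)
  tr <- sapply(c(latencies, rep(NA, n_silent)), function(lat) {
    v <- rep(baseline, length(time))
    if (!is.na(lat)) v[time >= window_start + lat &
                      time < window_start + lat + 1] <- 20
    v
  })
  trace_set(time, tr, "voltage", stim_times = c(window_start, 100),
            protocol = list(frequency = 20))
}

test_that("burst metrics follow their definitions", {
  # all silent: sc = 0, sp = 0, fssd undefined, amd from passive trace
  silent <- mk_traces(numeric(0), n_silent = 10)
  m0 <- burst_metrics(silent)
  expect_equal(m0$sc, 0)
  expect_equal(m0$sp, 0)
  expect_true(is.na(m0$fssd))
  expect_equal(m0$amd, 0, tolerance = 1e-9)
  # identical latencies: sp = 1, fssd = 0
  same <- mk_traces(rep(5, 10))
  m1 <- burst_metrics(same)
  expect_equal(m1$sp, 1)
  expect_equal(m1$fssd, 0, tolerance = 1e-9)
  # latencies 2, 3, 4 ms: sample SD = 1 (n-1 denominator)
  m2 <- burst_metrics(mk_traces(c(2, 3, 4)))
  expect_equal(m2$fssd, 1, tolerance = 0.02)
  expect_equal(m2$sc, 1)
  expect_error(burst_metrics(same, window = c(60, 60)), "window")
})

test_that("compound gain normalization spans 0 to 4", {
  df <- data.frame(frequency = c(10, 50, 100, 500),
                   sc = c(0, 1, 2, 4),
                   sp = c(0, 0.4, 0.8, 1),
                   fssd = c(4, 2, 1, 0.5),
                   amd = c(2, 6, 10, 14))
  gc <- normalize_and_compound(df)
  expect_equal(gc$gain[1], 0)        # everything at its worst
  expect_equal(gc$gain[4], 4)        # everything at its best
  expect_true(all(gc$gain >= 0 & gc$gain <= 4))
  # single varying metric: cGI range collapses to 1
  df2 <- df
  df2$sp <- 0.5; df2$fssd <- 2; df2$amd <- 7
  gc2 <- normalize_and_compound(df2)
  expect_equal(diff(range(gc2$gain)), 1)
  # undefined fssd normalizes to the worst case 0
  df3 <- df
  df3$fssd[2] <- NA
  gc3 <- normalize_and_compound(df3)
  expect_equal(gc3$components$fssd[2], 0)
})

test_that("sigmoid fit identifies exact and noisy generator parameters", {
  freqs <- c(10, 20, 50, 100, 200, 500)
  g <- gain_sigmoid(freqs, 1, 3, 50, 4)
  fit <- fit_gain_sigmoid(list(frequencies = freqs, gain = g))
  expect_equal(fit$A1, 1, tolerance = 1e-6)
  expect_equal(fit$A2, 3, tolerance = 1e-6)
  expect_equal(fit$fc, 50, tolerance = 1e-6)
  expect_equal(fit$power, 4, tolerance = 1e-5)
  # midpoint property g(fc) = (A1 + A2)/2
  expect_equal(gain_sigmoid(fit$fc, fit$A1, fit$A2, fit$fc, fit$power),
               (fit$A1 + fit$A2) / 2)
  # scale equivariance: scaling the gains scales A1, A2, not fc or power
  fit2 <- fit_gain_sigmoid(list(frequencies = freqs, gain = 2.5 * g))
  expect_equal(fit2$A1, 2.5 * fit$A1, tolerance = 1e-5)
  expect_equal(fit2$A2, 2.5 * fit$A2, tolerance = 1e-5)
  expect_equal(fit2$fc, fit$fc, tolerance = 1e-4)
  expect_equal(fit2$power, fit$power, tolerance = 1e-3)
  # a high-pass generator yields A2 > A1
  expect_gt(fit$A2, fit$A1)
})

test_that("fc recovery stays within 10% median error at sigma = 0.1", {
  set.seed(21)
  freqs <- exp(seq(log(10), log(500), length.out = 10))
  errs <- replicate(200, {
    fc_true <- runif(1, 25, 120)
    g <- gain_sigmoid(freqs, 1, 3, fc_true, 4) + rnorm(10, 0, 0.1)
    fit <- fit_gain_sigmoid(list(frequencies = freqs, gain = g))
    abs(fit$fc - fc_true) / fc_true
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("gain summary reports cutoff, maximum and relative gain changes", {
  mk <- function(A1, A2, fc) structure(list(A1 = A1, A2 = A2, fc = fc,
                                            power = 4),
                                       class = "sigmoid_fit")
  same <- gain_summary(mk(1, 3, 50), mk(1, 3, 50))
  expect_equal(same$dfc_pct, 0)
  expect_equal(same$dmax_gain_pct, 0)
  expect_equal(same$drelative_gain_pct, 0)
  expect_equal(same$relative_gain_pre, 2)       # (3 - 1)/1
  shifted <- gain_summary(mk(1, 3, 105), mk(1, 3, 76))
  expect_equal(shifted$dfc_pct, 100 * (76 - 105) / 105,
               tolerance = 1e-12)               # about -27.6%
  flagged <- gain_summary(mk(0, 3, 50), mk(1, 3, 50))
  expect_true(is.na(flagged$relative_gain_pre))
})

test_that("cutoff histogram uses left-closed bins and conserves counts", {
  fcs <- c(5, 20, 20.1, 45, 150, 499)
  h <- cutoff_histogram(fcs)
  expect_equal(sum(h$count), length(fcs))
  # an fc exactly on an edge lands in the bin to its right
  expect_equal(h$count[h$bin == "[20,50)"], 3L)
  expect_equal(h$count[h$bin == "[0,20)"], 1L)
  single <- cutoff_histogram(c(30, 35, 40))
  expect_equal(sum(single$count > 0), 1L)
})
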