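test_that("fit_passive recovers noiseless generator parameters within 1%", {
  tt <- gen_vc_transient(Cm_pF = 2.4, Rm_GOhm = 2.3, Rs_MOhm = 17.5,
                         noise_frac = 0, seed = 1)
  fp <- fit_passive(tt$time, tt$current, 10)
  expect_equal(fp$Cm_pF, 2.4, tolerance = 0.01)
  expect_equal(fp$Rm_GOhm, 2.3, tolerance = 0.01)
  expect_equal(fp$Rs_MOhm, 17.5, tolerance = 0.01)
  expect_error(fit_passive(tt$time, tt$current, 0), "nonzero")
})

test_that("fit_passive flags the pure-resistor degenerate limit", {
  time <- seq(0, 100, by = 0.05)
  flat <- rep(5, length(time)) + stats::rnorm(length(time), 0, 0.02)
  expect_warning(fp <- fit_passive(time, flat, 10), "pure-resistor")
  expect_equal(fp$Cm_pF, 0)
  expect_equal(fp$tau_us, 0)
})

test_that("fit_passive recovers randomized parameters under 2% noise", {
  set.seed(123)
  err <- matrix(NA_real_, 100, 3)
  for (i in 1:100) {
    cm <- runif(1, 1.5, 5); rm_ <- runif(1, 1, 4); rs <- runif(1, 8, 30)
    tt <- gen_vc_transient(cm, rm_, rs, noise_frac = 0.02)
    fp <- fit_passive(tt$time, tt$current, 10)
    err[i, ] <- abs(c(fp$Cm_pF / cm, fp$Rm_GOhm / rm_,
                      fp$Rs_MOhm / rs) - 1)
  }
  expect_lt(stats::median(err[, 1]), 0.05)
  expect_lt(stats::median(err[, 2]), 0.05)
  expect_lt(stats::median(err[, 3]), 0.05)
})

test_that("epsc_peaks measures baseline-subtracted amplitudes", {
  time <- seq(0, 100, by = 0.05)
  flat <- list(time = time, traces = rep(0, length(time)))
  expect_true(all(epsc_peaks(flat, c(20, 60)) < 1e-12))
  cfg <- synth_config(noise_current_pA = 0, amplitude_cv = 0,
                      amplitude_pA = 29.7)
  ts <- gen_epsc_train(30, cfg, n_trials = 1, seed = 1)
  pk <- epsc_peaks(ts, 30)
  expect_equal(pk[1, 1], 29.7, tolerance = 0.1 / 29.7)
  # second stimulus scaled by r gives amplitude ratio r
  ts2 <- gen_epsc_train(c(30, 60), cfg, ppr_profile = c(1, 0.6),
                        n_trials = 1, seed = 1)
  pk2 <- epsc_peaks(ts2, c(30, 60))
  expect_equal(pk2[2, 1] / pk2[1, 1], 0.6, tolerance = 0.01)
  expect_error(epsc_peaks(ts2, c(30, 35)), "overlap")
})

test_that("ppr reports second/first with the expected direction", {
  cfg <- synth_config(noise_current_pA = 0, amplitude_cv = 0)
  same <- gen_epsc_train(c(30, 50), cfg, ppr_profile = c(1, 1),
                         n_trials = 1)
  expect_equal(ppr(same, c(30, 50)), 1, tolerance = 0.01)
  fac <- gen_epsc_train(c(30, 50), cfg, ppr_profile = c(1, 1.3),
                        n_trials = 1)
  expect_gt(ppr(fac, c(30, 50)), 1)
  expect_error(ppr(same, 30), "exactly two")
})

test_that("presynaptic depression yields ppr < 1 without facilitation", {
  for (p0 in c(0.1, 0.3, 0.42, 0.7, 0.95)) {
    prm <- release_params(p0, tau_rec = 50, tau_facil = 1e-6,
                          tau_inact = 0.5)
    rel <- release_train(c(0, 20), prm)
    expect_lt(rel[1, 2] / rel[1, 1], 1)
  }
})

test_that("percent_change arithmetic and antisymmetry", {
  expect_equal(percent_change(c(100, 100), c(100, 100))$change, 0)
  expect_equal(percent_change(100, 128.5)$change, 28.5)
  expect_equal(percent_change(100, 63.2)$change, -36.8)
  expect_error(percent_change(numeric(0), 1), "empty")
  set.seed(4)
  a <- runif(20, 50, 150); b <- runif(20, 50, 150)
  expect_equal(percent_change(a, b)$change,
               -percent_change(b, a)$change * mean(b) / mean(a))
})

test_that("classification uses the +/-5% dead band", {
  expect_equal(classify_plasticity(28.5), "ltp")
  expect_equal(classify_plasticity(-36.8), "ltd")
  expect_equal(classify_plasticity(1), "none")
  expect_equal(classify_plasticity(-4.9), "none")
  out <- plasticity_outcome(pre_epsc = rep(100, 10),
                            post_epsc = rep(128.5, 10),
                            pre_ppr = rep(0.78, 10),
                            post_ppr = rep(0.57, 10))
  expect_equal(out$classification, "ltp")
  expect_lt(out$ppr_change, 0)
})
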