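test_that("generators are deterministic given config and seed", {
  a <- gen_vc_transient(seed = 5)
  b <- gen_vc_transient(seed = 5)
  expect_identical(a$current, b$current)
  c1 <- gen_epsc_train(c(20, 40), n_trials = 3, seed = 9)
  c2 <- gen_epsc_train(c(20, 40), n_trials = 3, seed = 9)
  expect_identical(c1$traces, c2$traces)
  d1 <- gen_burst_responses(50, n_trials = 3, seed = 2)
  d2 <- gen_burst_responses(50, n_trials = 3, seed = 2)
  expect_identical(d1$traces, d2$traces)
})

test_that("clamp transient follows the two-resistor closed form", {
  tt <- gen_vc_transient(2.4, 2.3, 17.5, dV_mV = 10, noise_frac = 0)
  expect_equal(tt$current[1], 10 / (17.5 / 1000))      # peak dV/Rs
  expect_equal(utils::tail(tt$current, 1),
               10 / (17.5 / 1000 + 2.3), tolerance = 1e-6)  # plateau
  tau_expected <- 2.4 * (17.5 / 1000) * 2.3 / (17.5 / 1000 + 2.3)
  expect_equal(unname(tt$truth["tau_ms"]), tau_expected)
  # sampling at 20 kHz
  expect_equal(tt$time[2] - tt$time[1], 0.05)
})

test_that("EPSC trains honor amplitude, ppr profile and superposition", {
  cfg <- synth_config(noise_current_pA = 0, amplitude_cv = 0)
  one <- gen_epsc_train(30, cfg, n_trials = 1)
  expect_equal(min(one$traces), -cfg$amplitude_pA,
               tolerance = 0.005)   # discretization < 0.5%
  pair <- gen_epsc_train(c(30, 50), cfg, n_trials = 1)
  expect_equal(unname(ppr(pair, c(30, 50))), 0.78, tolerance = 0.01)
  # well-separated events superpose independently
  far <- gen_epsc_train(c(30, 120), cfg, ppr_profile = c(1, 1),
                        n_trials = 1, duration_ms = 200)
  pk <- epsc_peaks(far, c(30, 120))
  expect_equal(pk[1, 1], pk[2, 1], tolerance = 0.005)
})

test_that("burst responses realize the configured spike statistics", {
  cfg0 <- synth_config()
  cfg0$sp_profile[c("A1", "A2")] <- c(0, 0)       # no spiking
  quiet <- gen_burst_responses(100, cfg0, n_trials = 5, seed = 3)
  m0 <- burst_metrics(quiet)
  expect_equal(m0$sp, 0)
  expect_equal(m0$sc, 0)
  cfg1 <- synth_config(jitter_ms = 0)
  cfg1$sp_profile[c("A1", "A2")] <- c(1, 1)       # always spike, no jitter
  loud <- gen_burst_responses(100, cfg1, n_trials = 5, seed = 3)
  m1 <- burst_metrics(loud)
  expect_equal(m1$sp, 1)
  expect_equal(m1$fssd, 0, tolerance = 1e-9)
  expect_gte(m1$sc, 1)
})

test_that("gain analysis recovers the generator cutoff end-to-end", {
  cfg <- synth_config(seed = 17)
  freqs <- c(10, 20, 35, 50, 80, 120, 200, 320, 400, 500)
  metrics <- lapply(freqs, function(f)
    burst_metrics(gen_burst_responses(f, cfg, n_trials = 10,
                                      seed = 17 + f)))
  curve <- normalize_and_compound(metrics)
  fit <- fit_gain_sigmoid(curve)
  expect_equal(fit$fc, 43.2, tolerance = 0.15)   # within 15% (stochastic)
  expect_gt(fit$A2, fit$A1)                      # high-pass behavior
})

test_that("plasticity effects scale the generator as configured", {
  cfg <- synth_config()
  expect_identical(apply_plasticity_effect(cfg, "control"), cfg)
  ltp <- apply_plasticity_effect(cfg, "ltp")
  expect_equal(ltp$amplitude_pA, 29.7 * 1.285)
  expect_equal(ltp$ppr, 0.78 * (1 - 0.274))
  expect_lt(ltp$sp_profile[["fc"]], cfg$sp_profile[["fc"]])
  expect_gt(ltp$amd_profile[["A2"]], cfg$amd_profile[["A2"]])
  ltd <- apply_plasticity_effect(cfg, "ltd")
  expect_equal(ltd$amplitude_pA, 29.7 * (1 - 0.368))
  expect_equal(ltd$ppr, 0.78 * 1.238)
  expect_gt(ltd$sp_profile[["fc"]], cfg$sp_profile[["fc"]])
  # plain-number worked example: LTP turns 100 into 128.5, LTD into 63.2
  cfg100 <- synth_config(amplitude_pA = 100)
  expect_equal(apply_plasticity_effect(cfg100, "ltp")$amplitude_pA, 128.5)
  expect_equal(apply_plasticity_effect(cfg100, "ltd")$amplitude_pA, 63.2)
})

test_that("synthetic gain curves are exact at zero noise and unbiased", {
  freqs <- c(10, 30, 100, 300)
  g0 <- gen_gain_curve(1, 3, 50, 4, freqs, noise_sd = 0, n_reps = 1)
  expect_equal(as.numeric(g0$gain), gain_sigmoid(freqs, 1, 3, 50, 4))
  gm <- gen_gain_curve(1, 3, 50, 4, freqs, noise_sd = 0.2,
                       n_reps = 4000, seed = 8)
  expect_equal(colMeans(gm$gain), gain_sigmoid(freqs, 1, 3, 50, 4),
               tolerance = 0.01)
  expect_equal(gain_sigmoid(50, 1, 3, 50, 4), 2)  # midpoint (A1+A2)/2
})
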