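test_that("configuration and wiring respect the circuit ranges", {
  expect_error(circuit_config(n_mf = 5), "n_mf")
  expect_error(circuit_config(n_goc = -1), "n_goc")
  cfg <- circuit_config(n_mf = 3, n_goc = 2, stochastic = FALSE,
                        calibrate_mf_goc = FALSE)
  circ <- wire_circuit(cfg)
  cls <- vapply(circ$synapses, function(s) s$class, character(1))
  # one excitatory dendritic synapse per mossy fiber
  expect_equal(sum(cls == "mf_grc"), 3L)
  # every mf drives every GoC; PF and AA feedback per GoC; each GoC
  # contacts all four dendritic glomeruli
  expect_equal(sum(cls == "mf_goc"), 6L)
  expect_equal(sum(cls == "pf_goc"), 2L)
  expect_equal(sum(cls == "aa_goc"), 2L)
  expect_equal(sum(cls == "goc_grc"), 8L)
  # per-site conductance split: gmax = 1200/nrel AMPA, 18800/nrel NMDA
  mfsyn <- circ$synapses[[which(cls == "mf_grc")[1]]]
  expect_equal(mfsyn$receptors[[1]]$gmax * 1e6, 1200)
  expect_equal(mfsyn$receptors[[1]]$gmax * 1e6 / mfsyn$n_sites, 200)
  expect_equal(mfsyn$receptors[[2]]$gmax * 1e6 / mfsyn$n_sites,
               18800 / 6)
  # all synapses carry the 1 ms transmission delay
  expect_true(all(vapply(circ$synapses, function(s) s$delay,
                         numeric(1)) == 1))
  # plasticity toggles only release probabilities
  cfg_ltp <- circuit_config(n_mf = 3, n_goc = 2, stochastic = FALSE,
                            plasticity = list(mf_grc = "ltp"),
                            calibrate_mf_goc = FALSE)
  circ_ltp <- wire_circuit(cfg_ltp)
  s0 <- circ$synapses[[which(cls == "mf_grc")[1]]]
  s1 <- circ_ltp$synapses[[which(cls == "mf_grc")[1]]]
  expect_equal(s1$p, 0.63)
  expect_equal(s0$p, 0.42)
  expect_equal(s1[c("tau_rec", "tau_facil", "tau_inact", "n_sites")],
               s0[c("tau_rec", "tau_facil", "tau_inact", "n_sites")])
})

test_that("a circuit without Golgi cells has no inhibitory synapses", {
  cfg <- circuit_config(n_mf = 2, n_goc = 0, stochastic = FALSE)
  circ <- wire_circuit(cfg)
  cls <- vapply(circ$synapses, function(s) s$class, character(1))
  expect_false(any(cls %in% c("goc_grc", "mf_goc", "pf_goc", "aa_goc")))
  expect_equal(length(circ$cells), 1L)
})

test_that("removing inhibition never decreases the spike count", {
  count_spikes <- function(n_goc) {
    cfg <- circuit_config(n_mf = 3, n_goc = n_goc, stochastic = FALSE)
    ts <- run_burst(wire_circuit(cfg), burst_protocol(100, n_trials = 2),
                    seed = 4)
    m <- burst_metrics(ts)
    m$sc
  }
  expect_gte(count_spikes(0), count_spikes(3))
})

test_that("runs are bit-reproducible under identical seeds and configs", {
  cfg <- circuit_config(n_mf = 2, n_goc = 1, stochastic = TRUE)
  circ <- wire_circuit(cfg)
  a <- run_burst(circ, burst_protocol(50, n_trials = 2), seed = 7)
  b <- run_burst(circ, burst_protocol(50, n_trials = 2), seed = 7)
  expect_identical(a$traces, b$traces)
  # and stochastic release produces trial-to-trial variability
  expect_gt(max(abs(a$traces[, 1] - a$traces[, 2])), 0.1)
})

test_that("burst runs hold the pre-stimulus potential at -65 mV", {
  cfg <- circuit_config(n_mf = 2, n_goc = 2, stochastic = TRUE)
  circ <- wire_circuit(cfg)
  ts <- run_burst(circ, burst_protocol(50, n_trials = 2), seed = 2)
  base <- stats::median(ts$traces[ts$time < 90, ])
  expect_lt(abs(base + 65), 0.5)
})

test_that("voltage clamp resolves EPSCs and a flat holding current", {
  cfg <- circuit_config(n_mf = 1, n_goc = 0, stochastic = FALSE)
  circ <- wire_circuit(cfg)
  quiet <- run_voltage_clamp(circ, stim_times = numeric(0), t_stop = 100)
  i <- quiet$traces[quiet$time > 20, 1]
  expect_lt(stats::sd(i), 1)          # flat holding current
  paired <- run_voltage_clamp(circ, stim_times = c(50, 70),
                              t_stop = 150)
  pk <- epsc_peaks(paired, c(50, 70))
  expect_true(all(pk > 2))            # two resolvable EPSCs
  ii <- paired$traces[, 1]
  tt <- paired$time
  t1 <- tt[tt > 50 & tt <= 60][which.min(ii[tt > 50 & tt <= 60])]
  t2 <- tt[tt > 70 & tt <= 80][which.min(ii[tt > 70 & tt <= 80])]
  expect_equal(t2 - t1, 20, tolerance = 0.15)
})

test_that("the calibrated mf-GoC synapse yields a -66 pA EPSC", {
  cfg <- circuit_config(n_mf = 1, n_goc = 1, stochastic = FALSE)
  circ <- wire_circuit(cfg)
  peak <- mf_goc_epsc_peak(cfg, circ$mf_goc_scale)
  expect_equal(peak, -66, tolerance = 0.05)
})

test_that("TBS delivers 80 stimuli on the printed schedule", {
  st <- tbs_times(tbs_protocol())
  expect_length(st, 80L)                       # 10 x 8
  onsets <- st[seq(1, 80, by = 10)]
  expect_equal(diff(onsets), rep(250, 7))      # bursts every 250 ms
  expect_equal(diff(st[1:10]), rep(10, 9))     # 100 Hz within burst
  expect_equal(max(st) - min(st), 7 * 250 + 9 * 10)
  cfg <- circuit_config(n_mf = 1, n_goc = 0, stochastic = FALSE)
  run <- run_tbs(wire_circuit(cfg), record_every = 40L)
  expect_length(run$stim_times, 80L)
  expect_gt(max(run$traces$traces), -64)       # responses present
})

test_that("LTP depolarizes burst responses more than control at 100 Hz", {
  amd_of <- function(mode) {
    cfg <- circuit_config(n_mf = 3, n_goc = 2, stochastic = FALSE,
                          plasticity = list(mf_grc = mode))
    ts <- run_burst(wire_circuit(cfg), burst_protocol(100, n_trials = 2),
                    seed = 3)
    burst_metrics(ts)$amd
  }
  a_ctrl <- amd_of("control")
  expect_gt(amd_of("ltp"), a_ctrl)
  expect_lt(amd_of("ltd"), a_ctrl)
})
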