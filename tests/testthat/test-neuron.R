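test_that("gating steady state and time constant follow alpha/beta", {
  sym <- channel_def("sym", list(list(z = 1, kind = "hh",
    alpha = list("exp", 0.5, -40, 20), beta = list("exp", 0.5, -40, 20))),
    erev = -80)
  gs <- gating_steady_state(sym, -55)
  expect_equal(gs$x_inf, 0.5)   # alpha == beta by construction
  nobeta <- channel_def("nb", list(list(z = 1, kind = "hh",
    alpha = list("exp", 2, -40, 25), beta = list("sigmoid", 0, 0, 5))),
    erev = -80)
  gs2 <- gating_steady_state(nobeta, -40)
  expect_equal(gs2$x_inf, 1)
  expect_equal(gs2$tau, 1 / 2)
  # forward integration of dx/dt = (x_inf - x)/tau converges to x_inf
  ch <- channel_registry()$kdr
  gs3 <- gating_steady_state(ch, -30)
  x <- 0
  for (i in 1:20000) x <- x + 1e-3 * (gs3$x_inf - x) / gs3$tau
  expect_equal(x, gs3$x_inf, tolerance = 1e-4)
  # registry steady states stay in [0, 1] over the physiological range
  for (ch in channel_registry()) {
    if (!length(ch$particles)) next
    for (V in seq(-100, 40, by = 10)) {
      gs <- gating_steady_state(ch, V, ca = 5e-4)
      expect_true(all(gs$x_inf >= 0 & gs$x_inf <= 1))
      expect_true(all(gs$tau > 0))
    }
  }
})

test_that("q10_scale implements the Q10 power law", {
  expect_equal(q10_scale(7, 3, 30, 30), 7)
  expect_equal(q10_scale(2, 3, 27, 37), 6)
  expect_equal(q10_scale(1, 2.4, 23, 37), 2.4^1.4)
})

test_that("calcium shell update has the analytic fixed points", {
  sh <- calcium_shell(depth_nm = 200, beta_ca = 0.6, ca0_nM = 100)
  area <- 1e-7
  expect_equal(step_calcium(100, 0, sh, area, 5), 100)
  # relaxation to rest at rate beta_ca
  expect_equal(step_calcium(500, 0, sh, area, 2),
               100 + 400 * exp(-0.6 * 2))
  # constant current: steady state ca0 - I/(2 F A d beta) (inward I < 0)
  Ic <- -10  # pA
  influx <- -(Ic * 1e-3) * 1e-6 / (2 * 96485.3329 * area * 200e-7) * 1e6
  steady <- 100 + influx / 0.6
  ca <- 100
  for (i in 1:200) ca <- step_calcium(ca, Ic, sh, area, 5)
  expect_equal(ca, steady, tolerance = 1e-6)
})

test_that("passive compartment charges like an RC circuit", {
  cell <- make_passive_cell(1, g_leak_nS = 1)
  # zero conductance/input: V stays put
  cell0 <- make_passive_cell(1, g_leak_nS = 0, v_init = -55)
  o0 <- simulate_cell(cell0, 50)
  expect_equal(max(abs(o0$v + 55)), 0, tolerance = 1e-9)
  # current step: V(t) = E + (I/g)(1 - exp(-t/tau)), tau = C/g
  I <- 0.01                              # nA
  out <- simulate_cell(cell, 100, bias = I)
  C_nF <- cylinder_cm_nF(10, 20)
  tau <- C_nF / 1e-3                     # g = 1 nS = 1e-3 uS
  vref <- -70 + (I / 1e-3) * (1 - exp(-out$time / tau))
  err <- max(abs(out$v - vref)) / (I / 1e-3)
  expect_lt(err, 0.001)                  # within 0.1% of the step size
})

test_that("two-compartment cable matches a fine-step reference", {
  cell <- make_passive_cell(2, g_leak_nS = 0.5)
  coarse <- simulate_cell(cell, 50, dt = 0.025, bias = 0.01,
                          record_every = 40L)
  fine <- simulate_cell(cell, 50, dt = 5e-4, bias = 0.01,
                        record_every = 2000L)
  stopifnot(length(coarse$v) == length(fine$v))
  rng <- diff(range(fine$v))
  expect_lt(max(abs(coarse$v - fine$v)) / rng, 0.005)
})

test_that("all-equal reversal potentials attract V from any start", {
  cell <- make_passive_cell(3, g_leak_nS = 1, erev = -62, v_init = -100)
  out <- simulate_cell(cell, 400)
  expect_equal(utils::tail(out$v, 1), -62, tolerance = 1e-6)
})

test_that("granule cell rests at -70 mV and fires with current injection", {
  grc <- build_grc()
  out <- simulate_cell(grc, 1000, record_every = 20L)
  expect_lt(abs(utils::tail(out$v, 1) + 70), 1)
  expect_length(out$spikes, 0)
  o2 <- simulate_cell(grc, 500, bias = 0.008, record_every = 10L)
  expect_gt(length(o2$spikes), 3)
  expect_true(all(is.finite(o2$v)))
  expect_true(all(o2$v > -120 & o2$v < 80))
})

test_that("granule-cell adaptations reproduce the quoted densities", {
  cfg <- grc_config()
  grc <- build_grc(cfg)
  area <- pi * (cfg$geometry$soma$diam_um * 1e-4)^2
  kir <- grc$channels[grc$channels$channel == "kir", ]
  expect_equal(kir$gbar_nS * 1e-9 / area * 1e6, 1350, tolerance = 0.01)
  dend_area <- 16 * pi * (0.75e-4) * (15 / 4 * 1e-4)
  lkg2 <- grc$channels[grc$channels$channel == "lkg2", ]
  expect_equal(sum(lkg2$gbar_nS) * 1e-9 / dend_area * 1e6, 60,
               tolerance = 0.01)
})

test_that("Golgi cell matches the printed capacitances and pacemakes", {
  goc <- build_goc()
  expect_equal(total_capacitance(goc), 145, tolerance = 0.01)
  comps <- goc$comps
  area <- pi * ifelse(comps$sphere, (comps$diam_um * 1e-4)^2,
                      comps$diam_um * 1e-4 * comps$L_um * 1e-4)
  cap <- area * 1e6
  expect_equal(cap[comps$name == "soma"], 23, tolerance = 0.02)
  expect_equal(sum(cap[grepl("dend", comps$name)]), 32, tolerance = 0.02)
  expect_equal(cap[comps$name == "axon"], 90, tolerance = 0.02)
  out <- simulate_cell(goc, 2000, record_every = 20L)
  expect_gt(length(out$spikes), 10)   # autonomous repetitive firing
})

test_that("passive Golgi input resistance matches the steady-state solve", {
  goc <- build_goc(passive_only = TRUE)
  I <- -0.02
  out <- simulate_cell(goc, 4000, bias = I, record_every = 100L)
  rin_sim <- (utils::tail(out$v, 1) - (-60)) / I  # mV/nA = MOhm
  # independent linear steady-state oracle on the 5-compartment network
  comps <- goc$comps
  area <- pi * ifelse(comps$sphere, (comps$diam_um * 1e-4)^2,
                      comps$diam_um * 1e-4 * comps$L_um * 1e-4)
  gl <- area / 47.6e3 * 1e6  # uS per compartment
  n <- nrow(comps)
  G <- diag(gl)
  for (i in 2:n) {
    half <- function(j) if (comps$sphere[j]) comps$diam_um[j] / 2
                        else comps$L_um[j] / 2
    Lc <- (half(i) + half(1)) * 1e-4
    ga <- pi * (comps$diam_um[i] / 2 * 1e-4)^2 / (100 * Lc) * 1e6
    G[i, i] <- G[i, i] + ga
    G[1, 1] <- G[1, 1] + ga
    G[1, i] <- G[1, i] - ga
    G[i, 1] <- G[i, 1] - ga
  }
  dv <- solve(G, c(I, rep(0, n - 1)))
  expect_equal(rin_sim, dv[1] / I, tolerance = 0.01)
})

test_that("halving the integration step changes subthreshold traces < 0.5% RMS", {
  cfg <- circuit_config(n_mf = 1, n_goc = 0, stochastic = FALSE)
  c1 <- wire_circuit(cfg, dt = 0.025)
  c2 <- wire_circuit(cfg, dt = 0.0125)
  p <- burst_protocol(100, n_trials = 1)
  t1 <- run_burst(c1, p, record_every = 8L, seed = 5)
  t2 <- run_burst(c2, p, record_every = 16L, seed = 5)
  stopifnot(nrow(t1$traces) == nrow(t2$traces))
  rng <- diff(range(t2$traces))
  rms <- sqrt(mean((t1$traces - t2$traces)^2))
  expect_lt(rms / rng, 0.005)
})

test_that("temperature classes change the simulated dynamics", {
  cfg <- grc_config()
  cfg37 <- cfg; cfg37$temperature <- 37
  g30 <- build_grc(cfg)
  g37 <- build_grc(cfg37)
  o30 <- simulate_cell(g30, 200, bias = 0.008, record_every = 10L)
  o37 <- simulate_cell(g37, 200, bias = 0.008, record_every = 10L)
  expect_gt(max(abs(o30$v - o37$v)), 1)  # Q10 adaptation has an effect
})
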