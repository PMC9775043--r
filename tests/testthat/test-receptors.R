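schemes <- build_default_schemes()

test_that("default schemes carry the printed rate constants", {
  tr <- schemes$ampa$transitions
  expect_equal(tr$rate[tr$from == "C" & tr$to == "O"], 5.4)
  expect_equal(tr$rate[tr$from == "O" & tr$to == "C"], 0.82)
  expect_equal(tr$rate[tr$from == "O" & tr$to == "D"], 1.12)
  expect_equal(tr$rate[tr$from == "D" & tr$to == "O"], 0.013)
  expect_equal(schemes$ampa$KB, 0.44)
  tn <- schemes$nmda$transitions
  expect_equal(tn$rate[tn$from == "C0" & tn$to == "C1"], 5)
  expect_equal(tn$rate[tn$from == "C1" & tn$to == "C2"], 5)
  expect_equal(tn$rate[tn$from == "C2" & tn$to == "O"], 0.03)
  expect_equal(tn$rate[tn$from == "O" & tn$to == "C2"], 0.966)
  expect_equal(tn$rate[tn$from == "C2" & tn$to == "D"], 0.00012)
  expect_equal(tn$rate[tn$from == "D" & tn$to == "C2"], 0.009)
  # generator structure: every rate matrix has zero row sums
  for (s in schemes) {
    Q <- scheme_rate_matrix(s, 0.7)
    expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  }
})

test_that("transmitter waveform superposes pulse and diffusion components", {
  tp <- transmitter_params(Ts_max = 1, Td_max = 0.3, pulse_duration = 1,
                           diff_tau = 1.2)
  none <- transmitter_waveform(list(time = numeric(0),
                                    amount = numeric(0)), tp,
                               seq(0, 10, 0.1))
  expect_true(all(none == 0))
  one <- list(time = 0, amount = 1)
  expect_equal(transmitter_waveform(one, tp, 0), 1 + 0.3)
  expect_equal(transmitter_waveform(one, tp, 0.5),
               1 + 0.3 * exp(-0.5 / 1.2))
  # amount scales both components
  half <- list(time = 0, amount = 0.42)
  expect_equal(transmitter_waveform(half, tp, 0), 0.42 * 1.3)
  # diffusion-only view drops the pulse
  expect_equal(transmitter_waveform(one, tp, 0.5, "diffusion"),
               0.3 * exp(-0.5 / 1.2))
  # superposition of two events
  two <- list(time = c(0, 5), amount = c(1, 0.5))
  t <- seq(0, 12, 0.05)
  expect_equal(transmitter_waveform(two, tp, t),
               transmitter_waveform(list(time = 0, amount = 1), tp, t) +
               transmitter_waveform(list(time = 5, amount = 0.5), tp, t))
})

test_that("AMPA drive S is monotone, bounded in [0,1)", {
  T <- seq(0, 20, by = 0.05)
  S <- ampa_drive(T)
  expect_true(all(S >= 0 & S < 1))
  expect_true(all(diff(S) > 0))
})

test_that("scheme stepping matches matrix-exponential propagation", {
  for (nm in names(schemes)) {
    s <- schemes[[nm]]
    occ <- scheme_init(s)
    Q <- scheme_rate_matrix(s, 1.0)
    # 100 steps of dt = 0.025 at constant T vs a single expm jump
    got <- occ
    for (i in 1:100) got <- step_scheme(got, s, 1.0, 0.025)
    ref <- scheme_expm_oracle(occ, Q, 2.5)
    expect_equal(unname(got), ref, tolerance = 1e-6)
  }
})

test_that("long-time occupancy reaches the null-space stationary state", {
  for (nm in c("ampa", "nmda")) {
    s <- schemes[[nm]]
    occ <- scheme_init(s)
    for (i in 1:4000) occ <- step_scheme(occ, s, 1.0, 0.5)
    st <- scheme_stationary_oracle(scheme_rate_matrix(s, 1.0))
    expect_equal(unname(occ), st, tolerance = 1e-5)
  }
})

test_that("occupancy is conserved under random transmitter input", {
  set.seed(11)
  s <- schemes$nmda
  occ <- scheme_init(s)
  ok <- TRUE
  for (i in 1:10000) {
    T <- stats::rexp(1, 2) * (stats::runif(1) < 0.2)
    occ <- step_scheme(occ, s, T, stats::runif(1, 0.01, 0.5))
    ok <- ok && all(occ >= 0 & occ <= 1)
  }
  expect_true(ok)
  expect_lt(abs(sum(occ) - 1), 1e-9)
  # no transmitter, all occupancy unbound: nothing moves
  o0 <- scheme_init(s)
  expect_equal(step_scheme(o0, s, 0, 1), o0, tolerance = 1e-12)
})

test_that("receptor current follows I = gmax * O * B * (V - Vrev)", {
  s <- schemes$ampa
  s$gmax <- 200
  occ <- c(C = 0.5, O = 0.5, D = 0)
  expect_equal(receptor_current(occ, s, -70), -7)  # pA
  expect_equal(receptor_current(occ, s, s$Vrev), 0)
  occ0 <- c(C = 1, O = 0, D = 0)
  expect_equal(receptor_current(occ0, s, -70), 0)
})

test_that("magnesium block suppresses NMDA current at rest and is monotone in V", {
  V <- seq(-90, 40, by = 5)
  B <- mg_block(V)
  expect_true(all(diff(B) > 0))
  expect_lt(mg_block(-70), 0.06)
  n <- schemes$nmda
  occ <- stats::setNames(c(0, 0, 0.5, 0.5, 0), n$state_names)
  blocked <- receptor_current(occ, n, -70)
  n_noblock <- n; n_noblock$mg_block <- FALSE
  free <- receptor_current(occ, n_noblock, -70)
  expect_lt(abs(blocked), 0.06 * abs(free) * 1.05)
})

test_that("temperature adaptation scales scheme rates by the receptor Q10", {
  a30 <- adapt_scheme_temperature(schemes$ampa, 30)
  f <- 2.4^((30 - 37) / 10)
  expect_equal(a30$transitions$rate, schemes$ampa$transitions$rate * f)
})
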