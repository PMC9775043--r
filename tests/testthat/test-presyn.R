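mf_grc <- release_params(p_init = 0.42, tau_rec = 8, tau_facil = 5,
                         tau_inact = 1, n_sites = 6L)

test_that("spike jump rules follow the printed depression/facilitation scheme", {
  s0 <- release_state(X = 1, Y = 0, Z = 0, P = 0.42)
  r <- apply_spike(s0, mf_grc)
  expect_equal(r$released, 0.42)
  expect_equal(r$state$X, 0.58)
  expect_equal(r$state$Y, 0.42)
  # facilitation jump applied after release: P' = P + p*(1-P)
  expect_equal(r$state$P, 0.42 + 0.42 * (1 - 0.42))  # 0.6636

  # P = 0: nothing released, facilitation jump still applies
  s <- release_state(X = 0.7, Y = 0.1, Z = 0.2, P = 0)
  r0 <- apply_spike(s, mf_grc)
  expect_equal(r0$released, 0)
  expect_equal(r0$state$X, 0.7)
  expect_equal(r0$state$P, 0.42)

  # P = 1 empties the available pool
  s1 <- release_state(X = 0.3, Y = 0.5, Z = 0.2, P = 1)
  r1 <- apply_spike(s1, mf_grc)
  expect_equal(r1$released, 0.3)
  expect_equal(r1$state$X, 0)
})

test_that("evolve_state matches an RK4 oracle and handles edge cases", {
  s <- release_state(X = 0.58, Y = 0.42, Z = 0, P = 0.6636)
  got <- evolve_state(s, 20, mf_grc)
  ref <- tm_rk4_oracle(s, 20, mf_grc)
  expect_equal(got$X, ref$X, tolerance = 1e-6)
  expect_equal(got$Y, ref$Y, tolerance = 1e-6)
  expect_equal(got$Z, ref$Z, tolerance = 1e-6)
  expect_equal(got$P, ref$P, tolerance = 1e-6)

  # dt = 0 is the identity
  expect_identical(evolve_state(s, 0, mf_grc), s)
  expect_error(evolve_state(s, -1, mf_grc), "non-negative")

  # long evolution reaches the unique fixed point (X=1, P=p_init)
  far <- evolve_state(s, 50 * max(8, 5, 1), mf_grc)
  expect_equal(far$X, 1, tolerance = 1e-6)
  expect_equal(far$Y, 0, tolerance = 1e-6)
  expect_equal(far$Z, 0, tolerance = 1e-6)
  expect_equal(far$P, 0.42, tolerance = 1e-6)

  # degenerate tau_inact == tau_rec uses the limiting closed form
  pdeg <- release_params(0.5, tau_rec = 4, tau_facil = 5, tau_inact = 4)
  sd0 <- release_state(X = 0.5, Y = 0.3, Z = 0.2, P = 0.5)
  gd <- evolve_state(sd0, 6, pdeg)
  rd <- tm_rk4_oracle(sd0, 6, pdeg)
  expect_false(any(is.na(unlist(gd[c("X", "Y", "Z")]))))
  expect_equal(gd$X, rd$X, tolerance = 1e-6)
  expect_equal(gd$Z, rd$Z, tolerance = 1e-6)
})

test_that("closed form agrees with RK4 over random parameter/state draws", {
  set.seed(42)
  for (i in 1:100) {
    p <- release_params(p_init = runif(1, 0.05, 1),
                        tau_rec = runif(1, 2, 60),
                        tau_facil = runif(1, 1, 80),
                        tau_inact = runif(1, 0.1, 5))
    w <- runif(3); w <- w / sum(w)
    s <- release_state(X = w[1], Y = w[2], Z = w[3], P = runif(1))
    dt <- runif(1, 0.5, 30)
    got <- evolve_state(s, dt, p)
    ref <- tm_rk4_oracle(s, dt, p)
    expect_equal(got$X, ref$X, tolerance = 1e-6)
    expect_equal(got$Y, ref$Y, tolerance = 1e-6)
    expect_equal(got$Z, ref$Z, tolerance = 1e-6)
    expect_equal(got$P, ref$P, tolerance = 1e-6)
    expect_lt(abs(got$X + got$Y + got$Z - 1), 1e-9)
  }
})

test_that("resource conservation holds over arbitrary evolve/spike sequences", {
  set.seed(7)
  s <- release_state(P = 0.42)
  worst <- 0; pmin <- 1; pmax <- 0
  for (i in 1:200) {
    if (runif(1) < 0.5) {
      s <- evolve_state(s, runif(1, 0, 15), mf_grc)
    } else {
      s <- apply_spike(s, mf_grc)$state
    }
    worst <- max(worst, abs(s$X + s$Y + s$Z - 1))
    pmin <- min(pmin, s$P); pmax <- max(pmax, s$P)
  }
  expect_lt(worst, 1e-9)
  expect_gte(pmin, 0); expect_lte(pmax, 1)
})

test_that("release_train composes evolve and spike correctly", {
  expect_equal(ncol(release_train(numeric(0), mf_grc)), 0L)
  expect_error(release_train(c(10, 5), mf_grc), "increasing")

  # two spikes 20 ms apart: compose by hand with the same primitives
  tr <- release_train(c(0, 20), mf_grc)
  s <- release_state(P = NA_real_)
  r1 <- apply_spike(s, mf_grc)
  s2 <- evolve_state(r1$state, 20, mf_grc)
  r2 <- apply_spike(s2, mf_grc)
  expect_equal(unname(tr[1, 1]), r1$released)
  expect_equal(unname(tr[1, 2]), r2$released)
  # paired-pulse ratio of the release amounts (depression-dominated here)
  expect_equal(unname(tr[1, 2] / tr[1, 1]), r2$released / r1$released)

  # pure depression: facilitation off (tau_facil -> 0 limit approximated),
  # fast inactivation, slow recovery: release amounts non-increasing
  pdep <- release_params(0.6, tau_rec = 100, tau_facil = 1e-6,
                         tau_inact = 0.5)
  amts <- release_train(seq(0, 90, by = 10), pdep)[1, ]
  expect_true(all(diff(amts) <= 1e-12))
})

test_that("stochastic release is seeded, all-or-none, and unbiased in the mean", {
  p1 <- release_params(p_init = 1, n_sites = 25L)
  one <- release_train(0, p1, stochastic = TRUE, seed = 1)
  expect_true(all(one == 1))  # Bernoulli(1): every site releases fully

  a <- release_train(c(0, 20, 40), mf_grc, stochastic = TRUE, seed = 99)
  b <- release_train(c(0, 20, 40), mf_grc, stochastic = TRUE, seed = 99)
  expect_identical(a, b)

  # law of large numbers: site-averaged stochastic release converges to the
  # deterministic release fraction
  pbig <- release_params(p_init = 0.42, tau_rec = 8, tau_facil = 5,
                         tau_inact = 1, n_sites = 10000L)
  det <- release_train(c(0, 20), release_params(0.42, 8, 5, 1, 1L))
  sto <- release_train(c(0, 20), pbig, stochastic = TRUE, seed = 3)
  expect_lt(abs(colMeans(sto)[1] - det[1, 1]) / det[1, 1], 0.02)
  expect_lt(abs(colMeans(sto)[2] - det[1, 2]) / det[1, 2], 0.02)
})

test_that("apply_plasticity scales release probability by +/-50%", {
  mf <- release_params(0.42, 8, 5, 1)
  expect_equal(apply_plasticity(mf, "ltp")$p_init, 0.63)
  expect_equal(apply_plasticity(mf, "ltd")$p_init, 0.21)
  expect_equal(apply_plasticity(mf, "control")$p_init, 0.42)
  goc <- release_params(0.35, 36, 58.5, 0.1)
  expect_equal(apply_plasticity(goc, "ltp")$p_init, 0.525)
  expect_equal(apply_plasticity(goc, "ltd")$p_init, 0.175)
  # other parameters untouched
  expect_equal(apply_plasticity(goc, "ltp")$tau_rec, 36)
  # out-of-range result is an error
  expect_error(apply_plasticity(release_params(0.8), "ltp"), "outside")
})
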