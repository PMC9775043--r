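# Independent numerical oracles used across the suite.

# Brute-force RK4 integration of the three-state presynaptic system between
# spikes (no jumps), step 1e-3 ms. Independent of the package's closed form.
tm_rk4_oracle <- function(state, dt, params, step = 1e-3) {
  rhs <- function(t, y, p) {
    list(c(X =  y["Z"] / p$tau_rec,
           Y = -y["Y"] / p$tau_inact,
           Z =  y["Y"] / p$tau_inact - y["Z"] / p$tau_rec,
           P = -(y["P"] - p$p_init) / p$tau_facil))
  }
  y0 <- c(X = state$X, Y = state$Y, Z = state$Z, P = state$P)
  times <- seq(0, dt, by = step)
  if (times[length(times)] < dt) times <- c(times, dt)
  out <- deSolve::ode(y0, times, rhs, params, method = "rk4")
  as.list(out[nrow(out), c("X", "Y", "Z", "P")])
}

# Stationary distribution of a master-equation rate matrix via null space
# (eigen decomposition of the generator), independent of the stepping code.
scheme_stationary_oracle <- function(Q) {
  # occupancy evolves as do/dt = t(Q) %*% o with Q[i, j] = rate i -> j
  G <- t(Q)
  ev <- eigen(G)
  k <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, k])
  v / sum(v)
}

# Matrix-exponential propagation of occupancy at constant transmitter.
scheme_expm_oracle <- function(occ, Q, dt) {
  as.numeric(Matrix::expm(Matrix::Matrix(t(Q) * dt)) %*% occ)
}
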