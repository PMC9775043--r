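#' Presynaptic release parameters
#'
#' Parameter set for the three-state presynaptic resource model with
#' facilitation (Tsodyks-Markram scheme). The transmitter resource cycles
#' through available (X), released/inactive (Y) and recovered (Z) pools;
#' the dynamic release probability P relaxes towards its baseline `p_init`
#' between spikes and jumps by `p_init * (1 - P)` at each spike.
#'
#' Shipped synapse classes (see [synapse_classes()]) use the granular-layer
#' values: mossy fiber to granule cell p = 0.42, tau_rec = 8 ms,
#' tau_facil = 5 ms, tau_inact = 1 ms; Golgi cell to granule cell p = 0.35,
#' tau_rec = 36 ms, tau_facil = 58.5 ms, tau_inact = 0.1 ms.
#'
#' @param p_init baseline release probability, in (0, 1].
#' @param tau_rec recovery-from-depression time constant (ms), > 0.
#' @param tau_facil facilitation time constant (ms), > 0.
#' @param tau_inact transmitter inactivation time constant (ms), > 0.
#' @param n_sites number of independent release sites (integer >= 1).
#' @return An object of class `release_params`.
#' @export
release_params <- function(p_init = 0.42, tau_rec = 8, tau_facil = 5,
                           tau_inact = 1, n_sites = 1L) {
  stopifnot(is.numeric(p_init), length(p_init) == 1L,
            p_init > 0, p_init <= 1,
            tau_rec > 0, tau_facil > 0, tau_inact > 0,
            n_sites >= 1)
  structure(list(p_init = as.numeric(p_init),
                 tau_rec = as.numeric(tau_rec),
                 tau_facil = as.numeric(tau_facil),
                 tau_inact = as.numeric(tau_inact),
                 n_sites = as.integer(n_sites)),
            class = "release_params")
}

#' Presynaptic release state
#'
#' @param X available resource fraction.
#' @param Y released (inactive) resource fraction.
#' @param Z recovered resource fraction.
#' @param P current release probability.
#' @param t_last time of last update (ms).
#' @return An object of class `release_state`.
#' @export
release_state <- function(X = 1, Y = 0, Z = 0, P = NA_real_, t_last = 0) {
  stopifnot(X >= -1e-12, Y >= -1e-12, Z >= -1e-12,
            abs(X + Y + Z - 1) < 1e-9)
  structure(list(X = X, Y = Y, Z = Z, P = P, t_last = t_last),
            class = "release_state")
}

#' Plasticity mode descriptor
#'
#' Long-term plasticity is modeled as a purely presynaptic change: LTP
#' scales the baseline release probability up by `fraction` (default 50%),
#' LTD scales it down by the same fraction, so the mossy fiber-granule cell
#' synapse moves from 0.42 to 0.63 (LTP) or 0.21 (LTD).
#'
#' @param mode one of `"control"`, `"ltp"`, `"ltd"`.
#' @param fraction scaling fraction in (0, 1); default 0.5.
#' @return An object of class `plasticity_mode`.
#' @export
plasticity_mode <- function(mode = c("control", "ltp", "ltd"),
                            fraction = 0.5) {
  mode <- match.arg(tolower(mode), c("control", "ltp", "ltd"))
  stopifnot(fraction > 0, fraction < 1)
  structure(list(mode = mode, fraction = fraction),
            class = "plasticity_mode")
}

#' Evolve the release state between spikes (closed form)
#'
#' Advances (X, Y, Z, P) by `dt` under the inter-spike linear dynamics
#' dY/dt = -Y/tau_inact, dZ/dt = Y/tau_inact - Z/tau_rec,
#' dX/dt = Z/tau_rec, dP/dt = -(P - p_init)/tau_facil,
#' using the analytic solution so X + Y + Z is conserved exactly. The
#' degenerate case tau_inact == tau_rec uses the t*exp(-t/tau) limit.
#'
#' @param state a [release_state()].
#' @param dt time step (ms), >= 0.
#' @param params a [release_params()].
#' @return The evolved `release_state`.
#' @export
evolve_state <- function(state, dt, params) {
  stopifnot(inherits(state, "release_state"),
            inherits(params, "release_params"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0)
    stop("'dt' must be a single non-negative number")
  if (dt == 0) return(state)
  xyz <- tm_interval(state$X, state$Y, state$Z, dt,
                     params$tau_inact, params$tau_rec)
  P0 <- if (is.na(state$P)) params$p_init else state$P
  P <- params$p_init + (P0 - params$p_init) * exp(-dt / params$tau_facil)
  release_state(X = xyz[1], Y = xyz[2], Z = xyz[3], P = P,
                t_last = state$t_last + dt)
}

## analytic interval solution of the Y -> Z -> X cascade; conservation is
## enforced by reconstructing X = 1 - Y - Z
tm_interval <- function(X0, Y0, Z0, dt, tau_inact, tau_rec) {
  a <- 1 / tau_inact
  b <- 1 / tau_rec
  Y <- Y0 * exp(-a * dt)
  if (abs(a - b) < 1e-12 * max(a, b)) {
    Z <- (Z0 + a * Y0 * dt) * exp(-a * dt)
  } else {
    C <- a * Y0 / (b - a)
    Z <- (Z0 - C) * exp(-b * dt) + C * exp(-a * dt)
  }
  c(1 - Y - Z, Y, Z)
}

#' Apply a spike to the release state
#'
#' At a spike a proportion P of the available resource X is transferred to
#' the released pool Y (depression); the facilitation jump
#' P <- P + p_init * (1 - P) is applied after release, so release uses the
#' pre-jump probability.
#'
#' @param state a [release_state()].
#' @param params a [release_params()].
#' @return A list with elements `state` (updated [release_state()]) and
#'   `released` (the released fraction P*X).
#' @export
apply_spike <- function(state, params) {
  stopifnot(inherits(state, "release_state"),
            inherits(params, "release_params"))
  P <- if (is.na(state$P)) params$p_init else state$P
  released <- P * state$X
  new <- release_state(X = state$X - released,
                       Y = state$Y + released,
                       Z = state$Z,
                       P = P + params$p_init * (1 - P),
                       t_last = state$t_last)
  list(state = new, released = released)
}

#' Simulate release over a spike train
#'
#' Deterministic mode: each of the `n_sites` sites releases the fraction
#' P*X at every spike (all sites identical). Stochastic mode: each site
#' independently releases its full available resource X with Bernoulli
#' probability P (all-or-none site release); only releasing sites are
#' depleted. Facilitation (the P dynamics) is shared across sites since all
#' sites see the same spike train.
#'
#' @param spike_times strictly increasing spike times (ms).
#' @param params a [release_params()].
#' @param stochastic logical; all-or-none Bernoulli site release.
#' @param seed optional integer seed (applied via [set.seed()]) for the
#'   stochastic mode; `NULL` uses the current RNG stream.
#' @return A matrix of released fractions, `n_sites` rows by
#'   `length(spike_times)` columns, with the spike times as column names.
#' @export
release_train <- function(spike_times, params, stochastic = FALSE,
                          seed = NULL) {
  stopifnot(inherits(params, "release_params"))
  n <- length(spike_times)
  if (n == 0L)
    return(matrix(numeric(0), nrow = params$n_sites, ncol = 0L))
  if (n > 1L && any(diff(spike_times) <= 0))
    stop("'spike_times' must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  ns <- params$n_sites
  X <- rep(1, ns); Y <- rep(0, ns); Z <- rep(0, ns)
  P <- params$p_init
  out <- matrix(0, nrow = ns, ncol = n,
                dimnames = list(NULL, format(spike_times)))
  t_prev <- spike_times[1L]
  for (k in seq_len(n)) {
    dt <- spike_times[k] - t_prev
    if (dt > 0) {
      for (s in seq_len(ns)) {
        xyz <- tm_interval(X[s], Y[s], Z[s], dt,
                           params$tau_inact, params$tau_rec)
        X[s] <- xyz[1]; Y[s] <- xyz[2]; Z[s] <- xyz[3]
      }
      P <- params$p_init + (P - params$p_init) *
        exp(-dt / params$tau_facil)
    }
    if (stochastic) {
      fire <- stats::runif(ns) < P
      rel <- ifelse(fire, X, 0)
    } else {
      rel <- P * X
    }
    X <- X - rel; Y <- Y + rel
    out[, k] <- rel
    P <- P + params$p_init * (1 - P)
    t_prev <- spike_times[k]
  }
  out
}

#' Apply long-term plasticity to release parameters
#'
#' LTP multiplies the baseline release probability by (1 + fraction), LTD
#' by (1 - fraction); all other parameters are untouched. With the default
#' fraction of 0.5 the mossy fiber-granule cell synapse moves from 0.42 to
#' 0.63 (LTP) or 0.21 (LTD), and the Golgi-granule cell synapse from 0.35
#' to 0.525 or 0.175.
#'
#' @param params a [release_params()].
#' @param mode a [plasticity_mode()] or one of `"control"`, `"ltp"`,
#'   `"ltd"` (default fraction 0.5).
#' @return Updated `release_params`.
#' @export
apply_plasticity <- function(params, mode) {
  stopifnot(inherits(params, "release_params"))
  if (is.character(mode)) mode <- plasticity_mode(mode)
  stopifnot(inherits(mode, "plasticity_mode"))
  p <- switch(mode$mode,
              control = params$p_init,
              ltp = params$p_init * (1 + mode$fraction),
              ltd = params$p_init * (1 - mode$fraction))
  if (p <= 0 || p > 1)
    stop(sprintf("plasticity would set release probability to %.4g, outside (0, 1]", p))
  params$p_init <- p
  params
}

#' Named presynaptic parameter sets of the granular-layer synapses
#'
#' Returns the release parameter sets of the five synapse classes of the
#' simplified granular-layer circuit: `mf_grc` (mossy fiber to granule
#' cell), `mf_goc` (mossy fiber to Golgi cell; same vesicle cycling as
#' mf_grc), `pf_goc` (parallel fiber to Golgi cell, p = 0.1), `aa_goc`
#' (ascending axon to Golgi cell) and `goc_grc` (GABAergic Golgi to
#' granule cell).
#'
#' @param n_sites release sites per synapse (default 6).
#' @return Named list of [release_params()].
#' @export
synapse_classes <- function(n_sites = 6L) {
  list(
    mf_grc  = release_params(0.42, 8,    5,    1,   n_sites),
    mf_goc  = release_params(0.42, 8,    5,    1,   n_sites),
    pf_goc  = release_params(0.10, 8,    5,    1,   n_sites),
    aa_goc  = release_params(0.10, 8,    5,    1,   n_sites),
    goc_grc = release_params(0.35, 36,   58.5, 0.1, n_sites)
  )
}
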