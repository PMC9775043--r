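#' Transmitter waveform parameters
#'
#' The transmitter concentration seen by postsynaptic receptors combines a
#' brief synaptic pulse Ts (square, `pulse_duration` long) with a diffusion
#' (spillover) wave Td decaying exponentially with `diff_tau`. Both
#' components are scaled by the released resource fraction Y of the event,
#' so T(t) = Y * Ts_max * rect(t) + Y * Td_max * exp(-t/diff_tau).
#' Extrasynaptic NMDA receptors see only the diffusion component.
#'
#' @param Ts_max peak synaptic-pulse concentration (mM).
#' @param Td_max peak diffusion-wave concentration (mM).
#' @param pulse_duration synaptic pulse duration (ms).
#' @param diff_tau diffusion-wave decay time constant (ms).
#' @return An object of class `transmitter_params`.
#' @export
transmitter_params <- function(Ts_max = 1.0, Td_max = 0.3,
                               pulse_duration = 1.0, diff_tau = 1.2) {
  stopifnot(Ts_max >= 0, Td_max >= 0, pulse_duration > 0, diff_tau > 0)
  structure(list(Ts_max = Ts_max, Td_max = Td_max,
                 pulse_duration = pulse_duration, diff_tau = diff_tau),
            class = "transmitter_params")
}

#' Transmitter concentration at given times
#'
#' Superposes the two-component transmitter waveform of all release events.
#'
#' @param events data.frame or list with components `time` (ms) and
#'   `amount` (released resource fraction Y per event), time-sorted.
#' @param params a [transmitter_params()].
#' @param t times (ms) at which to evaluate the concentration.
#' @param component `"full"` (pulse + diffusion, e.g. AMPA) or
#'   `"diffusion"` (spillover only, e.g. extrasynaptic NMDA).
#' @return Concentration (mM) at each `t`.
#' @export
transmitter_waveform <- function(events, params, t,
                                 component = c("full", "diffusion")) {
  component <- match.arg(component)
  stopifnot(inherits(params, "transmitter_params"))
  times <- events$time
  amounts <- events$amount
  stopifnot(length(times) == length(amounts))
  if (length(times) > 1L && any(diff(times) < 0))
    stop("'events' must be time-sorted")
  out <- numeric(length(t))
  for (k in seq_along(times)) {
    rel <- t - times[k]
    on <- rel >= 0
    td <- ifelse(on, amounts[k] * params$Td_max * exp(-rel / params$diff_tau), 0)
    out <- out + td
    if (component == "full") {
      ts <- ifelse(on & rel < params$pulse_duration,
                   amounts[k] * params$Ts_max, 0)
      out <- out + ts
    }
  }
  out
}

#' Saturating AMPA transmitter drive
#'
#' The AMPA opening transition is driven by S = T^2 / (T + K_B)^2 with
#' K_B = 0.44 mM (binomial two-site binding); S is monotone in T and
#' saturates below 1.
#'
#' @param T transmitter concentration (mM), >= 0.
#' @param KB binding constant (mM).
#' @return Drive value in \[0, 1).
#' @export
ampa_drive <- function(T, KB = 0.44) {
  stopifnot(all(T >= 0), KB > 0)
  (T / (T + KB))^2
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' Standard sigmoidal block B(V) = 1 / (1 + exp(-0.062 V) * Mg / 3.57)
#' with extracellular magnesium in mM.
#'
#' @param V membrane potential (mV).
#' @param mg extracellular Mg2+ concentration (mM); default 1.2.
#' @return Unblock factor in (0, 1).
#' @export
mg_block <- function(V, mg = 1.2) {
  1 / (1 + exp(-0.062 * V) * mg / 3.57)
}

#' Construct a receptor kinetic scheme
#'
#' A Markov scheme whose occupancy evolves under the master equation with
#' transmitter-dependent transition rates. Each transition is driven by a
#' constant rate (`drive = "const"`, units ms^-1), linearly by transmitter
#' (`"T"`, units mM^-1 ms^-1) or by the saturating AMPA drive (`"S"`,
#' units ms^-1, see [ampa_drive()]).
#'
#' @param state_names character vector of state labels.
#' @param transitions data.frame with columns `from`, `to` (state labels),
#'   `rate` (base rate) and `drive` (`"const"`, `"T"` or `"S"`).
#' @param open_states labels of conducting states.
#' @param gmax maximal conductance (pS).
#' @param Vrev reversal potential (mV).
#' @param KB binding constant for the `"S"` drive (mM).
#' @param mg_block logical; apply the NMDA magnesium block to the current.
#' @param mg extracellular magnesium (mM), used when `mg_block` is TRUE.
#' @param transmitter `"full"` or `"diffusion"`: which component of the
#'   transmitter waveform this receptor senses.
#' @param q10 temperature class of the gating rates (default 2.4, receptor
#'   gating), applied relative to `t_orig`.
#' @param t_orig temperature (deg C) at which the rates are specified.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(state_names, transitions, open_states,
                           gmax, Vrev, KB = 0.44, mg_block = FALSE,
                           mg = 1.2, transmitter = c("full", "diffusion"),
                           q10 = 2.4, t_orig = 37) {
  transmitter <- match.arg(transmitter)
  stopifnot(is.data.frame(transitions),
            all(c("from", "to", "rate", "drive") %in% names(transitions)),
            all(transitions$rate >= 0),
            all(transitions$drive %in% c("const", "T", "S")),
            all(transitions$from %in% state_names),
            all(transitions$to %in% state_names),
            length(open_states) >= 1L,
            all(open_states %in% state_names),
            gmax >= 0)
  # connectivity: every state reachable from the first (undirected sense)
  adj <- unique(rbind(cbind(transitions$from, transitions$to),
                      cbind(transitions$to, transitions$from)))
  seen <- state_names[1L]
  repeat {
    nxt <- unique(adj[adj[, 1L] %in% seen, 2L])
    grown <- union(seen, nxt)
    if (length(grown) == length(seen)) break
    seen <- grown
  }
  if (!all(state_names %in% seen))
    stop("kinetic scheme transition graph is not connected")
  structure(list(state_names = state_names,
                 transitions = transitions,
                 open_states = open_states,
                 gmax = gmax, Vrev = Vrev, KB = KB,
                 mg_block = mg_block, mg = mg,
                 transmitter = transmitter,
                 q10 = q10, t_orig = t_orig),
            class = "kinetic_scheme")
}

#' Initial (resting) occupancy of a scheme
#'
#' All occupancy in the first state, conventionally the fully unbound
#' closed state.
#'
#' @param scheme a [kinetic_scheme()].
#' @return Named occupancy vector summing to 1.
#' @export
scheme_init <- function(scheme) {
  occ <- stats::setNames(numeric(length(scheme$state_names)),
                         scheme$state_names)
  occ[1L] <- 1
  occ
}

#' Generator (rate) matrix of a scheme at a transmitter concentration
#'
#' Returns Q with Q\[i, j\] the instantaneous rate from state i to state j
#' and diagonal such that rows sum to zero; occupancy evolves as
#' d occ/dt = t(Q) %*% occ.
#'
#' @param scheme a [kinetic_scheme()].
#' @param T transmitter concentration (mM).
#' @return Square rate matrix (ms^-1).
#' @export
scheme_rate_matrix <- function(scheme, T) {
  n <- length(scheme$state_names)
  Q <- matrix(0, n, n, dimnames = list(scheme$state_names,
                                       scheme$state_names))
  tr <- scheme$transitions
  for (k in seq_len(nrow(tr))) {
    r <- tr$rate[k] * switch(tr$drive[k],
                             const = 1,
                             T = T,
                             S = ampa_drive(T, scheme$KB))
    Q[tr$from[k], tr$to[k]] <- Q[tr$from[k], tr$to[k]] + r
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Advance scheme occupancy by one time step
#'
#' Integrates the master equation at (piecewise-constant) transmitter
#' concentration `T` over `dt`, substepping internally so the update is
#' accurate and occupancy never leaves \[0, 1\]; probability is conserved.
#'
#' @param occ occupancy vector (sums to 1).
#' @param scheme a [kinetic_scheme()].
#' @param T transmitter concentration (mM), >= 0.
#' @param dt time step (ms), > 0.
#' @return Updated occupancy vector.
#' @export
step_scheme <- function(occ, scheme, T, dt) {
  stopifnot(dt > 0, T >= 0, length(occ) == length(scheme$state_names),
            abs(sum(occ) - 1) < 1e-6)
  tr <- scheme$transitions
  drv <- match(tr$drive, c("const", "T", "S")) - 1L
  out <- scheme_step_cpp(as.numeric(occ),
                         match(tr$from, scheme$state_names) - 1L,
                         match(tr$to, scheme$state_names) - 1L,
                         as.numeric(tr$rate), drv, scheme$KB, T, dt)
  stats::setNames(out, scheme$state_names)
}

#' Summed open-state occupancy
#' @param occ occupancy vector.
#' @param scheme a [kinetic_scheme()].
#' @return Open probability O.
#' @export
open_occupancy <- function(occ, scheme) {
  sum(occ[scheme$open_states])
}

#' Receptor current from occupancy
#'
#' I = gmax * O * B(V) * (V - Vrev), with B(V) = 1 except for NMDA-type
#' schemes where B is the magnesium unblock sigmoid. With gmax in pS and V
#' in mV the current is returned in pA.
#'
#' @param occ occupancy vector.
#' @param scheme a [kinetic_scheme()].
#' @param V membrane potential (mV).
#' @return Current (pA; negative = inward for Vrev > V).
#' @export
receptor_current <- function(occ, scheme, V) {
  O <- open_occupancy(occ, scheme)
  B <- if (isTRUE(scheme$mg_block)) mg_block(V, scheme$mg) else 1
  scheme$gmax * O * B * (V - scheme$Vrev) / 1000
}

#' Default receptor scheme registry
#'
#' Builds the AMPA, NMDA, kainate and GABA-A (fast/slow) schemes of the
#' granular-layer synapse models:
#' \itemize{
#'   \item AMPA: three states C-O-D; opening C->O at 5.4 ms^-1 scaled by
#'     the saturating drive S = T^2/(T + 0.44)^2, closing 0.82 ms^-1,
#'     desensitization O->D 1.12 ms^-1, recovery 0.013 ms^-1.
#'   \item NMDA: unbound state plus two identical glutamate-bound closed
#'     states (binding 5 mM^-1 ms^-1, unbinding 0.1 ms^-1 for both steps),
#'     opening from the doubly-bound state at 0.03 ms^-1 (closing 0.966),
#'     desensitization entered from the second closed state
#'     (0.00012 ms^-1 in, 0.009 ms^-1 out). Largely extrasynaptic: driven
#'     by the diffusion wave only, with voltage-dependent magnesium block.
#'   \item Kainate: AMPA-derived with 20-fold slower recovery from
#'     desensitization, producing slow temporal summation.
#'   \item GABA-A fast/slow: two independent C-O-D schemes sharing the
#'     GABA transient, a fast (alpha1-like, transient) and a slow
#'     (alpha6-like, sustained) pathway; rate constants are calibrated
#'     surrogates exposed for configuration.
#' }
#'
#' Conductances: the mossy fiber-granule cell synapse uses gmax = 1200 pS
#' (AMPA) and 18800 pS (NMDA) divided equally across release sites.
#'
#' @return Named list of [kinetic_scheme()] objects.
#' @export
build_default_schemes <- function() {
  tr <- function(...) {
    d <- data.frame(...)
    d$drive <- as.character(d$drive); d
  }
  ampa <- kinetic_scheme(
    state_names = c("C", "O", "D"),
    transitions = tr(from = c("C", "O", "O", "D"),
                     to   = c("O", "C", "D", "O"),
                     rate = c(5.4, 0.82, 1.12, 0.013),
                     drive = c("S", "const", "const", "const")),
    open_states = "O", gmax = 1200, Vrev = 0, KB = 0.44)
  nmda <- kinetic_scheme(
    state_names = c("C0", "C1", "C2", "O", "D"),
    transitions = tr(from = c("C0", "C1", "C1", "C2", "C2", "O", "C2", "D"),
                     to   = c("C1", "C0", "C2", "C1", "O", "C2", "D", "C2"),
                     rate = c(5, 0.1, 5, 0.1, 0.03, 0.966, 0.00012, 0.009),
                     drive = c("T", "const", "T", "const", "const",
                               "const", "const", "const")),
    open_states = "O", gmax = 18800, Vrev = 0,
    mg_block = TRUE, transmitter = "diffusion")
  kainate <- kinetic_scheme(
    state_names = c("C", "O", "D"),
    transitions = tr(from = c("C", "O", "O", "D"),
                     to   = c("O", "C", "D", "O"),
                     rate = c(5.4, 0.82, 1.12, 0.013 / 20),
                     drive = c("S", "const", "const", "const")),
    open_states = "O", gmax = 600, Vrev = 0, KB = 0.44)
  gabaa_fast <- kinetic_scheme(
    state_names = c("C", "O", "D"),
    transitions = tr(from = c("C", "O", "O", "D"),
                     to   = c("O", "C", "D", "O"),
                     rate = c(1.5, 0.14, 0.05, 0.005),
                     drive = c("T", "const", "const", "const")),
    open_states = "O", gmax = 2500, Vrev = -65)
  gabaa_slow <- kinetic_scheme(
    state_names = c("C", "O", "D"),
    transitions = tr(from = c("C", "O", "O", "D"),
                     to   = c("O", "C", "D", "O"),
                     rate = c(0.4, 0.025, 0.01, 0.002),
                     drive = c("T", "const", "const", "const")),
    open_states = "O", gmax = 600, Vrev = -65)
  list(ampa = ampa, nmda = nmda, kainate = kainate,
       gabaa_fast = gabaa_fast, gabaa_slow = gabaa_slow)
}

#' Temperature-adapt a kinetic scheme
#'
#' Scales all transition rates by the receptor-gating Q10 factor from the
#' scheme's reference temperature to the simulation temperature.
#'
#' @param scheme a [kinetic_scheme()].
#' @param t_sim simulation temperature (deg C).
#' @return The adapted scheme (rates scaled; `t_orig` updated).
#' @export
adapt_scheme_temperature <- function(scheme, t_sim) {
  f <- q10_scale(1, scheme$q10, scheme$t_orig, t_sim)
  scheme$transitions$rate <- scheme$transitions$rate * f
  scheme$t_orig <- t_sim
  scheme
}
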