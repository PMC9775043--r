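#' Hodgkin-Huxley-style channel definition
#'
#' A voltage- (or calcium-) gated conductance g = gbar * prod(x_i^z_i),
#' where each gating particle x relaxes with first-order kinetics
#' dx/dt = (x_inf - x)/tau_x, x_inf = alpha/(alpha+beta),
#' tau_x = 1/(alpha+beta). Rate functions alpha and beta are parametric:
#' \itemize{
#'   \item `"exp"`: A * exp((V - V0)/K)
#'   \item `"sigmoid"`: A / (1 + exp((V - V0)/K))
#'   \item `"linoid"`: A * K * x/(1 - exp(-x)) with x = (V - V0)/K
#'     (equivalently A * (V - V0)/(1 - exp(-(V - V0)/K)); A and K may be
#'     jointly negative to express the mirrored form)
#' }
#' Calcium-dependent particles (`kind = "kca"`) use
#' alpha = A/(1 + Ka * exp(-V/Va)/ca), beta = A'/(1 + ca/(Kb * exp(-V/Vb)))
#' with the shell calcium concentration ca in mM.
#'
#' @param name channel label.
#' @param particles list of particles; each a list with `z` (exponent),
#'   `kind` ("hh" or "kca"), `alpha` and `beta`, each c(type, A, V0, K)
#'   with type one of "exp", "sigmoid", "linoid" (for "kca": c(A, K, Vs)).
#' @param erev reversal potential (mV) or the string `"ca"` for a Nernst
#'   potential computed from the local calcium shell.
#' @param q10_class one of `"gating"`, `"permeation"`; determines which
#'   Q10 base scales the rates (gating) when the model is
#'   temperature-adapted. Conductance scaling uses the permeation class.
#' @param is_ca logical; the channel carries calcium (feeds the shell).
#' @return An object of class `channel_def`.
#' @export
channel_def <- function(name, particles, erev, q10_class = "gating",
                        is_ca = FALSE) {
  for (p in particles) {
    stopifnot(p$z > 0, p$kind %in% c("hh", "kca"))
    if (p$kind == "hh") {
      stopifnot(p$alpha[[1]] %in% c("exp", "sigmoid", "linoid"),
                p$beta[[1]] %in% c("exp", "sigmoid", "linoid"))
      # rates must be non-negative over the physiological range
      for (v in seq(-120, 60, by = 5)) {
        if (hh_rate_r(p$alpha, v) < 0 || hh_rate_r(p$beta, v) < 0)
          stop(sprintf("channel '%s': negative rate at V = %g mV", name, v))
      }
    }
  }
  structure(list(name = name, particles = particles, erev = erev,
                 q10_class = q10_class, is_ca = is_ca),
            class = "channel_def")
}

rate_type_code <- function(type) {
  match(type, c("exp", "sigmoid", "linoid")) - 1L
}

hh_rate_r <- function(spec, V) {
  type <- spec[[1]]
  A <- as.numeric(spec[[2]]); V0 <- as.numeric(spec[[3]])
  K <- as.numeric(spec[[4]])
  x <- (V - V0) / K
  switch(type,
         exp = A * exp(x),
         sigmoid = A / (1 + exp(x)),
         linoid = if (abs(x) < 1e-6) A * K * (1 + x / 2)
                  else A * K * x / (1 - exp(-x)))
}

#' Steady state and time constant of a gating particle
#'
#' x_inf = alpha/(alpha + beta), tau = 1/(alpha + beta).
#'
#' @param channel a [channel_def()].
#' @param V membrane potential (mV).
#' @param ca shell calcium (mM), used by calcium-dependent particles.
#' @return data.frame with one row per particle: `x_inf`, `tau` (ms).
#' @export
gating_steady_state <- function(channel, V, ca = 1e-4) {
  stopifnot(inherits(channel, "channel_def"))
  out <- lapply(channel$particles, function(p) {
    if (p$kind == "kca") {
      a <- p$alpha[[1]] / (1 + p$alpha[[2]] * exp(-V / p$alpha[[3]]) / ca)
      b <- p$beta[[1]] / (1 + ca / (p$beta[[2]] * exp(-V / p$beta[[3]])))
    } else {
      a <- hh_rate_r(p$alpha, V)
      b <- hh_rate_r(p$beta, V)
    }
    if (a + b <= 0) stop("alpha + beta = 0: ill-defined gating at this V")
    data.frame(x_inf = a / (a + b), tau = 1 / (a + b))
  })
  do.call(rbind, out)
}

#' Q10 temperature scaling
#'
#' value * q10^((t_sim - t_orig)/10). Standard classes: 3 for ionic
#' channel gating, 2.4 for receptor gating, 1.5 for ionic channel
#' permeation, 1.3 for neurotransmitter diffusion, 3 for calcium pumps.
#'
#' @param value quantity to scale (a rate; divide time constants' scale or
#'   scale their reciprocal).
#' @param q10 Q10 base (> 0).
#' @param t_orig reference temperature (deg C).
#' @param t_sim simulation temperature (deg C).
#' @return Scaled value.
#' @export
q10_scale <- function(value, q10, t_orig, t_sim) {
  stopifnot(q10 > 0)
  value * q10^((t_sim - t_orig) / 10)
}

#' Calcium shell parameters
#'
#' First-order submembrane shell: d[Ca]/dt = -I_Ca/(2 F A d) -
#' beta_ca ([Ca] - ca0), lumping pumps, buffers and diffusion into the
#' clearance rate beta_ca.
#'
#' @param depth_nm shell depth (nm); default 200.
#' @param beta_ca clearance rate (ms^-1); default 0.6.
#' @param ca0_nM resting concentration (nM); default 100.
#' @return An object of class `calcium_shell`.
#' @export
calcium_shell <- function(depth_nm = 200, beta_ca = 0.6, ca0_nM = 100) {
  stopifnot(depth_nm > 0, beta_ca > 0, ca0_nM > 0)
  structure(list(depth_nm = depth_nm, beta_ca = beta_ca, ca0_nM = ca0_nM),
            class = "calcium_shell")
}

#' Advance a calcium shell by one step (closed form)
#'
#' Exponential update of the linear shell equation; concentration floored
#' at zero. `area_cm2` is the membrane area feeding the shell.
#'
#' @param ca current concentration (nM).
#' @param I_Ca calcium current (pA; negative = inward).
#' @param params a [calcium_shell()].
#' @param area_cm2 shell membrane area (cm^2).
#' @param dt time step (ms).
#' @return Updated concentration (nM).
#' @export
step_calcium <- function(ca, I_Ca, params, area_cm2, dt) {
  stopifnot(inherits(params, "calcium_shell"), dt > 0, area_cm2 > 0)
  d_cm <- params$depth_nm * 1e-7
  # influx in mM/ms for I in nA: -I * 1e-6 / (2 F A d); convert pA -> nA
  influx_mM <- -(I_Ca * 1e-3) * 1e-6 / (2 * 96485.3329 * area_cm2 * d_cm)
  influx_nM <- influx_mM * 1e6
  steady <- params$ca0_nM + influx_nM / params$beta_ca
  out <- steady + (ca - steady) * exp(-params$beta_ca * dt)
  max(out, 0)
}

#' Construct a compartmental cell model
#'
#' @param name cell label.
#' @param comps data.frame with columns `name`, `parent` (parent
#'   compartment name or NA for the root), `L_um` (length), `diam_um`,
#'   `sphere` (logical; area = pi d^2, no length), `cm_specific`
#'   (uF/cm^2) and `ra` (axial resistivity, Ohm cm).
#' @param channels data.frame with columns `channel` (registry name),
#'   `comp` (compartment name) and `gbar_nS` (absolute conductance, nS).
#' @param registry named list of [channel_def()]s.
#' @param ca_shell a [calcium_shell()] applied to every compartment
#'   bearing a calcium channel, or NULL.
#' @param erev named list of reversal potentials used by the registry
#'   (e.g. `list(na = 87.39, k = -84.69)`); entries referenced by name in
#'   channel `erev` strings are resolved here.
#' @param temperature simulation temperature (deg C).
#' @param t_orig temperature the channel rates refer to (deg C).
#' @param q10 named list of Q10 bases (`gating`, `permeation`,
#'   `ca_pump`).
#' @param cao extracellular calcium (mM).
#' @param v_init initial membrane potential (mV).
#' @param spike_threshold soma spike-detection threshold (mV).
#' @param bias constant somatic current injection (nA).
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(name, comps, channels, registry,
                       ca_shell = calcium_shell(),
                       erev = list(), temperature = 30, t_orig = 37,
                       q10 = list(gating = 3, permeation = 1.5,
                                  ca_pump = 3),
                       cao = 2, v_init = -70, spike_threshold = -20,
                       bias = 0) {
  stopifnot(is.data.frame(comps), is.data.frame(channels))
  stopifnot(all(comps$L_um > 0 | comps$sphere), all(comps$diam_um > 0))
  miss <- setdiff(unique(channels$channel), names(registry))
  if (length(miss))
    stop("missing channel definition(s): ", paste(miss, collapse = ", "))
  stopifnot(all(channels$comp %in% comps$name))
  # parent indices; require root first and parents before children
  pidx <- match(comps$parent, comps$name)
  if (sum(is.na(pidx)) != 1L)
    stop("compartment graph must have exactly one root")
  if (!all(is.na(pidx) | pidx < seq_len(nrow(comps))))
    stop("compartments must be ordered parents-before-children")
  structure(list(name = name, comps = comps, channels = channels,
                 registry = registry, ca_shell = ca_shell, erev = erev,
                 temperature = temperature, t_orig = t_orig, q10 = q10,
                 cao = cao, v_init = v_init,
                 spike_threshold = spike_threshold, bias = bias),
            class = "cell_model")
}

#' @exportS3Method base::print
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model '%s': %d compartments, %d channel placements, %g degC>\n",
              x$name, nrow(x$comps), nrow(x$channels), x$temperature))
  invisible(x)
}

comp_area_cm2 <- function(comps) {
  ifelse(comps$sphere,
         pi * (comps$diam_um * 1e-4)^2,
         pi * (comps$diam_um * 1e-4) * (comps$L_um * 1e-4))
}

#' Total membrane capacitance of a cell (pF)
#' @param cell a [cell_model()].
#' @return Capacitance in pF.
#' @export
total_capacitance <- function(cell) {
  sum(comp_area_cm2(cell$comps) * cell$comps$cm_specific) * 1e6
}

# Flatten a cell_model into the list consumed by the C++ integrator.
# Q10 adaptation (gating rates, permeation conductances, calcium pump
# clearance) is applied here, from cell$t_orig to cell$temperature.
flatten_cell <- function(cell, clamp_comp = NA, clamp_v = -70,
                         record_comp = 1L, bias = NULL) {
  comps <- cell$comps
  n <- nrow(comps)
  area <- comp_area_cm2(comps)
  cm <- area * comps$cm_specific * 1e3        # nF
  pidx <- match(comps$parent, comps$name)

  # axial conductance child -> parent through half-lengths (uS)
  g_ax <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(pidx[i])) next
    half_len <- function(j) {
      if (comps$sphere[j]) comps$diam_um[j] / 2 else comps$L_um[j] / 2
    }
    L_cm <- (half_len(i) + half_len(pidx[i])) * 1e-4
    r_cm <- comps$diam_um[i] / 2 * 1e-4
    g_S <- pi * r_cm^2 / (comps$ra[i] * L_cm)
    g_ax[i] <- g_S * 1e6
  }

  fg <- q10_scale(1, cell$q10$gating, cell$t_orig, cell$temperature)
  fp <- q10_scale(1, cell$q10$permeation, cell$t_orig, cell$temperature)
  fc <- q10_scale(1, cell$q10$ca_pump, cell$t_orig, cell$temperature)

  ch <- cell$channels
  nch <- nrow(ch)
  ch_comp <- match(ch$comp, comps$name) - 1L
  # permeation Q10 scales active conductances; passive leaks keep their
  # stated values (the printed membrane resistance holds as given)
  active <- vapply(ch$channel, function(nm)
    length(cell$registry[[nm]]$particles) > 0, logical(1))
  ch_gbar <- ch$gbar_nS * 1e-3 * ifelse(active, fp, 1)  # uS
  ch_erev <- numeric(nch)
  ch_np <- integer(nch)
  ch_is_ca <- integer(nch)
  pt <- list(z = numeric(0), kind = integer(0),
             atype = integer(0), btype = integer(0),
             aA = numeric(0), aV0 = numeric(0), aK = numeric(0),
             bA = numeric(0), bV0 = numeric(0), bK = numeric(0))
  for (i in seq_len(nch)) {
    def <- cell$registry[[ch$channel[i]]]
    ch_is_ca[i] <- as.integer(isTRUE(def$is_ca))
    er <- def$erev
    if (identical(er, "ca")) {
      ch_erev[i] <- NA_real_
    } else if (is.character(er)) {
      ch_erev[i] <- cell$erev[[er]]
    } else ch_erev[i] <- er
    ch_np[i] <- length(def$particles)
    for (p in def$particles) {
      pt$z <- c(pt$z, p$z)
      if (p$kind == "kca") {
        pt$kind <- c(pt$kind, 1L)
        pt$atype <- c(pt$atype, 0L); pt$btype <- c(pt$btype, 0L)
        pt$aA <- c(pt$aA, p$alpha[[1]] * fg)
        pt$aV0 <- c(pt$aV0, p$alpha[[2]])
        pt$aK <- c(pt$aK, p$alpha[[3]])
        pt$bA <- c(pt$bA, p$beta[[1]] * fg)
        pt$bV0 <- c(pt$bV0, p$beta[[2]])
        pt$bK <- c(pt$bK, p$beta[[3]])
      } else {
        pt$kind <- c(pt$kind, 0L)
        pt$atype <- c(pt$atype, rate_type_code(p$alpha[[1]]))
        pt$btype <- c(pt$btype, rate_type_code(p$beta[[1]]))
        pt$aA <- c(pt$aA, as.numeric(p$alpha[[2]]) * fg)
        pt$aV0 <- c(pt$aV0, as.numeric(p$alpha[[3]]))
        pt$aK <- c(pt$aK, as.numeric(p$alpha[[4]]))
        pt$bA <- c(pt$bA, as.numeric(p$beta[[2]]) * fg)
        pt$bV0 <- c(pt$bV0, as.numeric(p$beta[[3]]))
        pt$bK <- c(pt$bK, as.numeric(p$beta[[4]]))
      }
    }
  }

  # calcium shells on compartments with calcium channels
  ca_has <- integer(n)
  if (!is.null(cell$ca_shell) && any(ch_is_ca == 1L))
    ca_has[unique(ch_comp[ch_is_ca == 1L]) + 1L] <- 1L
  sh <- cell$ca_shell %||% calcium_shell()
  tK <- 273.15 + cell$temperature
  list(parent = ifelse(is.na(pidx), -1L, pidx - 1L),
       g_ax = g_ax, cm = cm,
       ch_comp = ch_comp, ch_gbar = ch_gbar, ch_erev = ch_erev,
       ch_np = ch_np, ch_is_ca = ch_is_ca,
       pt_z = pt$z, pt_kind = pt$kind,
       pt_atype = pt$atype, pt_btype = pt$btype,
       pt_aA = pt$aA, pt_aV0 = pt$aV0, pt_aK = pt$aK,
       pt_bA = pt$bA, pt_bV0 = pt$bV0, pt_bK = pt$bK,
       ca_has = ca_has,
       ca_depth = rep(sh$depth_nm * 1e-7, n),
       ca_beta = rep(sh$beta_ca * fc, n),
       ca0 = rep(sh$ca0_nM * 1e-6, n),
       ca_area = area,
       cao = cell$cao,
       eca_factor = 1000 * 8.314462 * tK / (2 * 96485.3329),
       bias = if (is.null(bias)) cell$bias else bias,
       clamp_comp = if (is.na(clamp_comp)) -1L
                    else match(clamp_comp, comps$name) - 1L,
       clamp_v = clamp_v,
       record_comp = record_comp - 1L,
       v_init = cell$v_init,
       spike_thr = cell$spike_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a single cell
#'
#' Integrates the compartmental model with exponential-Euler gating and an
#' implicit (backward-Euler) voltage update on the branched tree, default
#' dt = 0.025 ms.
#'
#' @param cell a [cell_model()].
#' @param t_stop simulation length (ms).
#' @param dt time step (ms).
#' @param bias constant somatic current (nA); overrides the cell's value.
#' @param clamp optional compartment name to voltage-clamp.
#' @param clamp_v clamp potential (mV).
#' @param record compartment index to record (1 = soma/root).
#' @param record_every record every k-th step.
#' @return A list with `time` (ms), `v` (mV at the recorded compartment),
#'   `i_clamp` (nA, if clamped), `spikes` (soma threshold crossings, ms).
#' @export
simulate_cell <- function(cell, t_stop, dt = 0.025, bias = NULL,
                          clamp = NULL, clamp_v = -70, record = 1L,
                          record_every = 1L) {
  fc <- flatten_cell(cell,
                     clamp_comp = if (is.null(clamp)) NA else clamp,
                     clamp_v = clamp_v, record_comp = record,
                     bias = bias)
  out <- sim_run_cpp(list(fc), list(), list(), dt, t_stop,
                     as.integer(record_every), 1.0, FALSE)
  list(time = out$time, v = out$v[, 1], i_clamp = out$i_clamp[, 1],
       spikes = out$spikes[[1]])
}

#' Solve the bias current holding a cell at a target potential
#'
#' Iteratively adjusts the constant somatic injection until the
#' steady-state somatic potential is within `tol` of `v_target`.
#'
#' @param cell a [cell_model()].
#' @param v_target target potential (mV).
#' @param tol tolerance (mV); default 0.3.
#' @param settle settling time per probe simulation (ms).
#' @param max_iter maximum secant iterations.
#' @return The bias current (nA).
#' @export
solve_bias <- function(cell, v_target, tol = 0.3, settle = 300,
                       max_iter = 8) {
  probe <- function(b) {
    out <- simulate_cell(cell, settle, bias = b, record_every = 10L)
    stats::median(utils::tail(out$v, 400))
  }
  b0 <- 0; v0 <- probe(b0)
  if (abs(v0 - v_target) < tol) return(b0)
  # crude input conductance estimate for the first secant step
  b1 <- b0 + (v_target - v0) * 0.002
  v1 <- probe(b1)
  for (i in seq_len(max_iter)) {
    if (abs(v1 - v_target) < tol) return(b1)
    if (abs(v1 - v0) < 1e-9) break
    b2 <- b1 + (v_target - v1) * (b1 - b0) / (v1 - v0)
    b0 <- b1; v0 <- v1
    b1 <- b2; v1 <- probe(b2)
  }
  if (abs(v1 - v_target) >= 2)
    stop(sprintf("bias solve failed: reached %.2f mV for target %.2f mV",
                 v1, v_target))
  b1
}
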