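#' Default voltage-gated channel registry
#'
#' Hodgkin-Huxley-style rate functions for the channel complement of the
#' granule-cell and Golgi-cell models: transient Na, delayed-rectifier K,
#' A-type K, inward-rectifier K, slow (M-like) K, high-voltage-activated
#' Ca, Ca-dependent K, persistent Na (Golgi pacemaking) and passive leaks.
#' The kinetics are configurable surrogates in the style of the cerebellar
#' granule-cell/Golgi-cell model family, specified at 37 degC; reversal
#' potentials are resolved against the cell's `erev` table (`na`, `k`,
#' `lkg1`, `gaba`, `goc_leak`), the Ca channel uses a Nernst potential
#' from the local shell.
#'
#' @return Named list of [channel_def()] objects.
#' @export
channel_registry <- function() {
  p <- function(z, a, b, kind = "hh") list(z = z, kind = kind,
                                           alpha = a, beta = b)
  list(
    na = channel_def("na", list(
      p(3, list("linoid", 0.32, -54, 4), list("linoid", -0.28, -27, -5)),
      p(1, list("exp", 0.2, -34, -18), list("sigmoid", 6, -11, -5))),
      erev = "na"),
    nap = channel_def("nap", list(
      p(1, list("sigmoid", 0.2, -50, -5), list("sigmoid", 0.2, -50, 5))),
      erev = "na"),
    goc_na = channel_def("goc_na", list(
      p(3, list("linoid", 0.32, -54, 4), list("linoid", -0.28, -27, -5)),
      p(1, list("exp", 0.128, -50, -18), list("sigmoid", 4, -27, -5))),
      erev = "na"),
    goc_kdr = channel_def("goc_kdr", list(
      p(4, list("linoid", 0.032, -52, 5), list("exp", 0.5, -57, -40))),
      erev = "k"),
    kdr = channel_def("kdr", list(
      p(4, list("linoid", 0.050, -55, 5), list("exp", 0.45, -60, -40))),
      erev = "k"),
    ka = channel_def("ka", list(
      p(3, list("sigmoid", 1.2, -35, -10), list("sigmoid", 1.2, -55, 10)),
      p(1, list("sigmoid", 0.04, -73, 6), list("sigmoid", 0.04, -73, -6))),
      erev = "k"),
    kir = channel_def("kir", list(
      p(1, list("exp", 0.13289, -83.94, -24.39),
        list("exp", 0.16994, -83.94, 35.714))),
      erev = "k"),
    kslow = channel_def("kslow", list(
      p(1, list("exp", 0.0033, -30, 40), list("exp", 0.0033, -30, -20))),
      erev = "k"),
    ca = channel_def("ca", list(
      p(2, list("exp", 0.04944, -29.06, 15.87),
        list("exp", 0.08298, -18.66, -25.641)),
      p(1, list("exp", 0.0013, -48, -18.183),
        list("exp", 0.0013, -48, 83.33))),
      erev = "ca", is_ca = TRUE),
    kca = channel_def("kca", list(
      p(1, list(2.5, 1.5e-3, 11.765), list(1.5, 1.5e-4, 12.987),
        kind = "kca")),
      erev = "k"),
    lkg1 = channel_def("lkg1", list(), erev = "lkg1",
                       q10_class = "permeation"),
    lkg2 = channel_def("lkg2", list(), erev = "gaba",
                       q10_class = "permeation"),
    goc_leak = channel_def("goc_leak", list(), erev = "goc_leak",
                           q10_class = "permeation")
  )
}

read_cell_yaml <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}

#' Granule-cell model configuration
#'
#' Reads the bundled granule-cell description: geometry (5.8 um soma,
#' four 15 um dendrites of 4 compartments, axon with 5 hillock and 30
#' distal compartments), the conductance table with its placements, the
#' adaptations (doubled GABA leak, 1.5x inward rectifier, leak reversal
#' calibrated so the cell rests at -70 mV) and the temperature/Q10
#' settings (simulation at 30 degC).
#'
#' @param path YAML file; default the bundled `grc_cell.yaml`.
#' @return Configuration list.
#' @export
grc_config <- function(path = system.file("extdata", "grc_cell.yaml",
                                          package = "grcgain")) {
  read_cell_yaml(path)
}

#' Golgi-cell model configuration
#' @param path YAML file; default the bundled `goc_cell.yaml`.
#' @return Configuration list.
#' @export
goc_config <- function(path = system.file("extdata", "goc_cell.yaml",
                                          package = "grcgain")) {
  read_cell_yaml(path)
}

#' Build the granule-cell model
#'
#' Assembles the multicompartmental granule cell from its configuration:
#' soma-placed K_A, K_IR (x1.5) and K_slow, axon-hillock Na and delayed
#' rectifier, dendritic-tip Ca and K_Ca with calcium shells, a leak in
#' every compartment and the GABAergic tonic leak (x2) on the dendrites.
#' The leak reversal is the calibrated value restoring a -70 mV resting
#' potential at the simulation temperature.
#'
#' @param config list from [grc_config()].
#' @return A [cell_model()].
#' @export
build_grc <- function(config = grc_config()) {
  g <- config$geometry
  rows <- list(data.frame(name = "soma", parent = NA_character_,
                          L_um = g$soma$diam_um, diam_um = g$soma$diam_um,
                          sphere = TRUE))
  dend_names <- character(0)
  for (i in seq_len(g$dendrites$count)) {
    for (j in seq_len(g$dendrites$n_comp)) {
      nm <- sprintf("dend%d_%d", i, j)
      pa <- if (j == 1) "soma" else sprintf("dend%d_%d", i, j - 1)
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm, parent = pa,
                   L_um = g$dendrites$L_um / g$dendrites$n_comp,
                   diam_um = g$dendrites$diam_um, sphere = FALSE)
      dend_names <- c(dend_names, nm)
    }
  }
  for (j in seq_len(g$axon$hillock$n_comp)) {
    nm <- sprintf("hillock%d", j)
    pa <- if (j == 1) "soma" else sprintf("hillock%d", j - 1)
    rows[[length(rows) + 1L]] <-
      data.frame(name = nm, parent = pa, L_um = g$axon$hillock$L_um,
                 diam_um = g$axon$diam_um, sphere = FALSE)
  }
  for (j in seq_len(g$axon$distal$n_comp)) {
    nm <- sprintf("axon%d", j)
    pa <- if (j == 1) sprintf("hillock%d", g$axon$hillock$n_comp)
          else sprintf("axon%d", j - 1)
    rows[[length(rows) + 1L]] <-
      data.frame(name = nm, parent = pa, L_um = g$axon$distal$L_um,
                 diam_um = g$axon$diam_um, sphere = FALSE)
  }
  comps <- do.call(rbind, rows)
  comps$cm_specific <- config$cm_specific
  comps$ra <- config$ra

  cs <- config$conductances_nS
  ad <- config$adaptations
  hillock <- sprintf("hillock%d", seq_len(g$axon$hillock$n_comp))
  axon <- sprintf("axon%d", seq_len(g$axon$distal$n_comp))
  tips <- sprintf("dend%d_%d", seq_len(g$dendrites$count), g$dendrites$n_comp)
  place <- function(channel, comp, total_nS) {
    data.frame(channel = channel, comp = comp,
               gbar_nS = total_nS / length(comp))
  }
  area <- comp_area_cm2(comps)
  channels <- rbind(
    place("na", hillock, cs$na),
    place("kdr", hillock, cs$kdr_hillock),
    place("kdr", axon, cs$kdr_axon),
    place("ka", "soma", cs$ka),
    place("kir", "soma", cs$kir * ad$kir_factor),
    place("kslow", "soma", cs$kslow),
    place("kca", tips, cs$kca),
    place("ca", tips, cs$ca),
    data.frame(channel = "lkg1", comp = comps$name,
               gbar_nS = cs$lkg1 * area / sum(area)),
    place("lkg2", dend_names, cs$lkg2 * ad$lkg2_factor)
  )
  cell_model("grc", comps, channels, channel_registry(),
             ca_shell = do.call(calcium_shell, config$calcium_shell),
             erev = config$erev,
             temperature = config$temperature, t_orig = config$t_orig,
             q10 = config$q10, cao = config$cao,
             v_init = config$v_init)
}

#' Build the Golgi-cell model
#'
#' Five compartments (27 um spherical soma, three 113 x 3 um dendrites,
#' one 1200 x 2.4 um axon; compartment capacitances 23/32/90 pF summing
#' to 145 pF), axial resistivity 100 Ohm cm, specific membrane resistance
#' 47.6 kOhm cm^2, with the active conductances placed in the soma. The
#' active set (Na, persistent Na, K_DR, K_A, K_slow, Ca, K_Ca) is an
#' HH-style surrogate of the source model's 12 somatic conductances and
#' produces autonomous pacemaking; the persistent Na current and leak
#' reversal drive the depolarization between spikes.
#'
#' @param config list from [goc_config()].
#' @param passive_only logical; strip active conductances (leak only),
#'   for passive input-resistance analysis.
#' @return A [cell_model()].
#' @export
build_goc <- function(config = goc_config(), passive_only = FALSE) {
  g <- config$geometry
  rows <- list(data.frame(name = "soma", parent = NA_character_,
                          L_um = g$soma$diam_um, diam_um = g$soma$diam_um,
                          sphere = TRUE))
  for (i in seq_len(g$dendrites$count)) {
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("dend%d", i), parent = "soma",
                 L_um = g$dendrites$L_um, diam_um = g$dendrites$diam_um,
                 sphere = FALSE)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(name = "axon", parent = "soma", L_um = g$axon$L_um,
               diam_um = g$axon$diam_um, sphere = FALSE)
  comps <- do.call(rbind, rows)
  comps$cm_specific <- config$cm_specific
  comps$ra <- config$ra

  # passive leak from the specific membrane resistance, every compartment
  area <- comp_area_cm2(comps)
  leak_nS <- area / config$rm_specific_kohm_cm2 * 1e6
  channels <- data.frame(channel = "goc_leak", comp = comps$name,
                         gbar_nS = leak_nS)
  if (!passive_only) {
    cs <- config$conductances_nS
    act <- data.frame(channel = names(cs), comp = "soma",
                      gbar_nS = as.numeric(unlist(cs)))
    channels <- rbind(channels, act)
  }
  cell_model("goc", comps, channels, channel_registry(),
             ca_shell = do.call(calcium_shell, config$calcium_shell),
             erev = config$erev,
             temperature = config$temperature, t_orig = config$t_orig,
             q10 = config$q10, cao = config$cao,
             v_init = config$v_init)
}

#' Calibrate the leak reversal potential for a target resting potential
#'
#' Adjusts the `lkg1` reversal by secant iteration on simulated
#' steady-state somatic voltage (no input, no bias), reproducing the
#' adjustment of the leakage reversal that restores the resting potential.
#'
#' @param cell a [cell_model()] whose registry uses the `lkg1` reversal.
#' @param v_target target resting potential (mV); default -70.
#' @param settle settling simulation length (ms).
#' @param tol tolerance (mV).
#' @return The calibrated cell, with attribute `"lkg1_erev"`.
#' @export
calibrate_leak_reversal <- function(cell, v_target = -70, settle = 600,
                                    tol = 0.1) {
  probe <- function(e) {
    cell$erev$lkg1 <- e
    out <- simulate_cell(cell, settle, record_every = 20L)
    utils::tail(out$v, 1)
  }
  e0 <- cell$erev$lkg1 %||% -60
  v0 <- probe(e0)
  e1 <- e0 + (v_target - v0) * 2
  v1 <- probe(e1)
  for (i in 1:12) {
    if (abs(v1 - v_target) < tol) break
    e2 <- e1 + (v_target - v1) * (e1 - e0) / (v1 - v0)
    e0 <- e1; v0 <- v1
    e1 <- e2; v1 <- probe(e2)
  }
  cell$erev$lkg1 <- e1
  attr(cell, "lkg1_erev") <- e1
  cell
}
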