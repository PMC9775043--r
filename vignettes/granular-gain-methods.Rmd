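---
title: "Methods: simulating gain modulation by long-term plasticity in the cerebellar granular layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granular-layer gain modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`grcgain` simulates how long-term potentiation (LTP) and depression
(LTD), expressed as changes in presynaptic release probability, retune
the gain and frequency bandwidth of burst transmission through the
cerebellar granular layer. The model chain is:

1. **Presynaptic resource dynamics** (`evolve_state`, `apply_spike`,
   `release_train`): the three-state scheme in which transmitter
   resources cycle through available (X), released (Y) and recovered (Z)
   pools with recovery constant `tau_rec`, inactivation `tau_inact`, and
   a dynamic release probability P that relaxes to its baseline p with
   constant `tau_facil` and jumps by `p (1 - P)` at each spike
   (facilitation). At a spike a proportion `P X` moves from X to Y
   (depression). Between spikes the system is linear and is advanced by
   its closed-form solution, so `X + Y + Z = 1` holds to machine
   precision; the degenerate case `tau_inact == tau_rec` uses the
   `t exp(-t/tau)` limit. The release side of each synapse carries six
   release sites; in stochastic mode each site releases its full
   available resource with Bernoulli probability P (all-or-none), and
   the postsynaptic conductance is split equally across sites, so the
   deterministic limit is recovered in the site average.
2. **Transmitter and receptors** (`transmitter_waveform`,
   `step_scheme`, `build_default_schemes`): each release event produces
   a two-component glutamate (or GABA) transient, a 1 ms synaptic pulse
   plus an exponentially decaying diffusion wave, both scaled by the
   released fraction Y. AMPA receptors see the full transient through
   the saturating drive `S = T^2/(T + 0.44 mM)^2`; the largely
   extrasynaptic NMDA receptors see only the diffusion component and
   carry the standard voltage-dependent magnesium block
   (1.2 mM Mg2+). Receptor gating is a Markov master equation; the
   AMPA scheme is C-O-D with opening 5.4 ms^-1 (times S), closing
   0.82 ms^-1, desensitization 1.12 / 0.013 ms^-1; the NMDA scheme has
   an unbound state, two identical glutamate-bound closed states
   (binding 5 mM^-1 ms^-1, unbinding 0.1 ms^-1), opening 0.03 /
   0.966 ms^-1 from the doubly-bound state and slow desensitization
   (0.00012 / 0.009 ms^-1) entered from the second closed state.
   Integration uses substepped RK4 when transmitter is present and a
   cached matrix-exponential propagator at rest, so occupancy is
   conserved and agrees with matrix-exponential propagation to 1e-6.
3. **Compartmental neurons** (`build_grc`, `build_goc`,
   `simulate_cell`): conductance-based cells integrated with
   exponential-Euler gating and an implicit (backward-Euler) voltage
   update solved directly on the branched tree (a Hines-ordered
   elimination), default `dt = 0.025` ms. Calcium-bearing compartments
   carry a submembrane shell `d[Ca]/dt = -I_Ca/(2 F A d) -
   beta ([Ca] - [Ca]0)` updated in closed form.
4. **Microcircuit** (`wire_circuit`, `run_burst`, `run_voltage_clamp`,
   `run_tbs`): one granule cell (GrC) with four dendrites, 1-4 mossy
   fibers (mfs, one per dendrite), 0-4 Golgi cells (GoCs) receiving
   feedforward mf drive and parallel-fiber/ascending-axon feedback from
   the GrC, and GABAergic GoC-GrC synapses in all four dendritic
   glomeruli. All synapses have a 1 ms transmission delay; GoC and GrC
   spikes are threshold crossings at -20 mV.

The analysis side mirrors a patch-clamp workflow: passive-parameter
extraction from clamp transients (`fit_passive`), EPSC amplitudes and
paired-pulse ratio (`epsc_peaks`, `ppr`), plasticity quantification
(`percent_change`, `classify_plasticity`), burst metrics and compound
gain index (`burst_metrics`, `normalize_and_compound`), and sigmoidal
gain-curve fitting `g(f) = (A1 - A2)/(1 + (f/fc)^p) + A2`
(`fit_gain_sigmoid`, `gain_summary`, `cutoff_histogram`).

# Fixed parameters and their provenance

The quantities the model takes as given: mf-GrC release probability
0.42 (LTP 0.63, LTD 0.21, i.e. +/-50%), `tau_rec` 8 ms, `tau_facil`
5 ms, `tau_inact` 1 ms; GoC-GrC release probability 0.35 (LTP 0.525,
LTD 0.175), `tau_rec` 36 ms, `tau_facil` 58.5 ms, `tau_inact` 0.1 ms;
parallel-fiber release probability 0.1; six release sites per synapse
with AMPA 1200 pS and NMDA 18800 pS divided across sites; GrC soma
5.8 um with four 15 um dendrites and a 5+30-compartment axon; the GrC
conductance table with its placements, the doubled GABA leak
(60 uS/cm^2), the 1.5x inward rectifier (1350 uS/cm^2) and the leak
reversal calibrated to a -70 mV rest; GoC geometry with 23/32/90 pF
compartments (145 pF total), 100 Ohm cm axial resistivity and
47.6 kOhm cm^2 membrane resistance; mf-GoC conductance calibrated to a
-66 pA single-stimulus EPSC; Q10 classes 3 (channel gating), 2.4
(receptor gating), 1.5 (permeation), 1.3 (transmitter diffusion), 3
(calcium clearance), applied from 37 degC model temperature to the
30 degC simulation temperature; stimulation protocols (five-pulse
bursts at 10-500 Hz, ten trials; theta-burst 10 pulses at 100 Hz,
eight bursts every 250 ms).

# Design choices where the design was open

Several components are deliberately package-authored surrogates,
exposed for configuration:

* **Voltage-gated kinetics.** The rate functions alpha(V), beta(V) of
  the GrC/GoC channel complement are parametric HH-style forms
  (exponential, sigmoid, linoid) in the style of the cerebellar
  granule/Golgi model family; only the conductance magnitudes and
  placements are fixed by the conductance table. The GrC sodium
  inactivation is positioned so the cell fires repetitively rather
  than depolarization-blocking during burst summation (rheobase
  ~8 pA, f-I up to ~120 Hz at 30 pA). Consequently, acceptance for the
  neuron layer is property-based (resting potential, capacitances,
  input resistance, convergence), not waveform-exact.
* **Facilitation equation.** The release-probability dynamics relax P
  toward its baseline p between spikes with jump `P <- P + p (1 - P)`,
  the canonical facilitation scheme; release uses the pre-jump P
  (depression computed first, facilitation applied after release).
* **Transmitter amplitudes.** Peak concentrations are not reported
  anywhere we could adopt them from, so `Ts_max = 0.6 mM`,
  `Td_max = 0.18 mM` were calibrated once so that a paired-mf stimulus
  depolarizes the GrC by ~11 mV, the measured mean EPSP; the mf-GrC
  EPSC then comes out near -13 pA per fiber and the EPSP near 6 mV for
  a single fiber. Both components scale with the released fraction Y.
* **GABA-A schemes.** The fast (alpha1-like, transient) and slow
  (alpha6-like, sustained) pathways are C-O-D surrogates whose binding
  rates sit in the linear (non-saturating) regime - essential, because
  a saturating scheme hides presynaptic plasticity from the
  postsynaptic side. Conductances (2500 / 600 pS per glomerular
  contact) are calibrated so that tonic GoC firing leaves the GrC able
  to spike under strong mf input while phasic inhibition still shapes
  the burst response.
* **Golgi pacemaking.** The GoC's slow afterhyperpolarization current
  (a Markov scheme in the source models) is represented by the
  Ca-dependent K conductance paired with a slow somatic calcium shell
  (clearance 0.015 ms^-1), which yields autonomous firing near 7 Hz;
  the GrC calcium shells keep the stated clearance of 0.6 ms^-1.
* **Wiring of inhibition.** Every GoC contacts all four dendritic
  glomeruli of the GrC (single-GoC inhibition is anatomically intense);
  with sparser wiring, GABAergic plasticity has almost no leverage on
  the gain curves.
* **Pre-stimulus settle.** Burst runs hold the GrC at -65 mV (bias
  current solved automatically) for 300 ms before the first pulse so
  that GoC pacemaking and the sustained GABA component reach steady
  state; the homeostatic effect of GABAergic plasticity acts largely
  through this standing inhibition.
* **Gain normalization across conditions.** Within one condition the
  four burst metrics are min-max normalized across frequencies and
  summed (compound gain index, 0-4). When comparing plasticity states,
  all conditions are normalized against the control extremes
  (`normalize_and_compound(reference = )`), since per-condition
  normalization would erase exactly the uniform gain shifts under
  study.
* **Analysis conventions.** EPSC analysis uses a 5 ms pre-stimulus
  baseline, a 10 ms peak window, extremum location on a 0.5 ms
  boxcar-smoothed trace with amplitude measured on the raw trace
  around that location (unbiased under additive noise); the
  paired-pulse ratio is second/first so depression gives values below
  1; plasticity classification uses a +/-5% dead band; first-spike
  jitter uses the n-1 denominator and normalizes to the worst case
  when fewer than two trials spike; the burst analysis window runs
  from the first stimulus to 50 ms after the last; cutoff histograms
  use left-closed bins at 0/20/50/100/200/500 Hz; sigmoid fits
  multi-start over fc in {10, 30, 50, 100, 200} Hz with the exponent
  started at 4 and bounded in [0.5, 20].

# What the synthetic-data generators emulate

`gen_vc_transient` produces the analytic series-resistance/membrane RC
response to a 10 mV clamp step at 20 kHz with peak-scaled Gaussian
noise. `gen_epsc_train` superposes double-exponential EPSCs (rise
0.3 ms, decay 3 ms) with per-stimulus scaling, trial-amplitude
variability (CV 5%) and 2 pA current noise. `gen_burst_responses`
builds an EPSP staircase whose peak follows a frequency sigmoid,
inserts spike bursts with a sigmoidal probability whose count grows
and whose first-spike jitter tightens along the same profile, and
superimposes a 1 ms triangular spike surrogate with 0.5 mV voltage
noise. `gen_gain_curve` draws noisy replicates of the gain sigmoid
directly. Defaults carry the measured population values (29.7 pA EPSC,
11.4 mV EPSP, PPR 0.78, compound-gain sigmoid A1 1.03 / A2 2.69 /
fc 43.2 Hz, LTP +28.5% EPSC and -27.4% PPR, LTD -36.8% and +23.8%).

These generators reproduce the statistical structure the analyses
assume - they do not emulate electrode artifacts, line noise, series
-resistance drift or cell-to-cell kinetic variability. A passing
closure test therefore shows the pipeline recovers what it is designed
to measure, not that it is robust to every pathology of real
recordings.

# Numerical choices

Voltage uses backward Euler on the tree (penalty rows implement an
ideal somatic voltage clamp; the electrode current is reconstructed
from the membrane and axial currents of the clamped compartment),
gating uses exponential Euler, receptor schemes use RK4 with
substepping bounded by the total escape rate, presynaptic and calcium
states use closed forms. Halving `dt` from 0.025 ms changes
subthreshold burst traces by well under 0.5% RMS. Spike detection uses
upward crossings of -20 mV with 1 ms refractory de-duplication. The
holding-current solves iterate a secant on 600 ms settle simulations to
0.25 mV. All randomness flows through R's RNG; trials use a
seed-plus-index stream, so runs are bit-reproducible.

# Problem sizes used in the shipped tests and workflow

The test-suite sweeps use five frequencies (20-500 Hz), two trials per
frequency in deterministic mode and two circuit presets; the analysis
workflow (`analysis/01` through `04`) uses seven frequencies, six to
eight stochastic trials and all four presets, which is where the
plasticity change tables come from. Parameter-recovery closures use 25
to 200 Monte-Carlo draws.

# Known limitations

* Channel kinetics are surrogates; quantities that depend on exact
  spike shape (e.g. precise cutoff values of the full model) are
  matched directionally, not numerically.
* The circuit is one GrC with lumped inputs: population statistics
  (cutoff histograms across cells, LTP incidence) cannot be reproduced,
  only the single-cell mechanism.
* Plasticity induction (the calcium/BCM side of theta-burst
  stimulation) is out of scope; `run_tbs` verifies protocol timing and
  responses, and plasticity expression is applied directly as
  release-probability scaling.
* The stochastic release model is site-level all-or-none; quantal
  variance beyond Bernoulli sites is not modeled.
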