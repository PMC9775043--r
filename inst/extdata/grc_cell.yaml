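# Granule-cell model description.
#
# Conductances are the printed absolute values (nS). The conductance table
# lists nine values against eight channel labels and nine placements; the
# two near-identical delayed-rectifier values (2.338 / 2.336) correspond to
# its duplicated placement (hillock and axon). The inward-rectifier value
# is independently confirmed by the density arithmetic: 0.951 nS over the
# 5.8 um soma is 900 uS/cm2, which the 1.5x adaptation brings to the quoted
# 1350 uS/cm2; likewise lkg2 x2 corresponds to the quoted 60 uS/cm2 GABA
# leak. The leak reversal (erev lkg1) is calibrated so the adapted cell
# rests at -70 mV at the 30 degC simulation temperature.
name: grc
temperature: 30.0
t_orig: 37.0
v_init: -70.0
cao: 2.0
cm_specific: 1.0      # uF/cm2
ra: 100.0             # Ohm cm
erev:
  na: 87.39
  k: -84.69
  lkg1: -50.249       # calibrated: resting potential -70 mV (see build_grc)
  gaba: -65.0
q10:
  gating: 3.0
  permeation: 1.5
  ca_pump: 3.0
calcium_shell:
  depth_nm: 200.0
  beta_ca: 0.6
  ca0_nM: 100.0
geometry:
  soma: {diam_um: 5.8}
  dendrites: {count: 4, L_um: 15.0, n_comp: 4, diam_um: 0.75}
  axon:
    diam_um: 0.75
    hillock: {n_comp: 5, L_um: 1.0}
    distal: {n_comp: 30, L_um: 2.0}
conductances_nS:
  na: 8.589           # axon hillock
  kdr_hillock: 2.338
  kdr_axon: 2.336
  ka: 3.382           # soma
  kir: 0.951          # soma (x1.5 adaptation applied at build)
  kca: 0.707          # dendritic endings
  ca: 0.108           # dendritic endings
  kslow: 0.264        # soma
  lkg1: 0.17          # all compartments, area-weighted
  lkg2: 0.042         # dendrites (x2 adaptation applied at build)
adaptations:
  kir_factor: 1.5
  lkg2_factor: 2.0
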