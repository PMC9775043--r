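# Golgi-cell model description: five compartments (spherical soma 27 um,
# three 113 x 3 um dendritic compartments, one 1200 x 2.4 um axonal
# compartment) whose capacitances come out at 23 / 32 / 90 pF (total
# 145 pF) with 1 uF/cm2; axial resistivity 100 Ohm cm; specific membrane
# resistance 47.6 kOhm cm2. All active conductances sit in the soma; the
# set is an HH-style surrogate of the source model's somatic complement,
# tuned for autonomous pacemaking (persistent Na + depolarized leak
# reversal drive the interspike depolarization, Ca/K_Ca shape the AHP).
name: goc
temperature: 30.0
t_orig: 37.0
v_init: -60.0
cao: 2.0
cm_specific: 1.0       # uF/cm2 (printed "1 mF/cm2" read as uF/cm2)
ra: 100.0              # Ohm cm
rm_specific_kohm_cm2: 47.6
erev:
  na: 87.39
  k: -84.69
  goc_leak: -60.0      # depolarized leak reversal: pacemaking drive
q10:
  gating: 3.0
  permeation: 1.5
  ca_pump: 3.0
calcium_shell:
  depth_nm: 200.0
  beta_ca: 0.015  # slow clearance: the K_Ca/shell pair stands in for the
                  # slow afterhyperpolarization current and paces firing
  ca0_nM: 100.0
geometry:
  soma: {diam_um: 27.0}
  dendrites: {count: 3, L_um: 113.0, diam_um: 3.0}
  axon: {L_um: 1200.0, diam_um: 2.4}
conductances_nS:       # somatic, surrogate set
  goc_na: 150.0
  nap: 2.0
  goc_kdr: 150.0
  ka: 10.0
  kslow: 15.0
  ca: 6.0
  kca: 60.0
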