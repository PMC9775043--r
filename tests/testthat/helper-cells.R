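# Passive test cells built directly through the public constructors.

passive_registry <- function() {
  list(leak = channel_def("leak", list(), erev = "leak",
                          q10_class = "permeation"))
}

# n_comp passive cylinders in a chain (first is the root), absolute leak
# per compartment g_leak_nS, leak reversal erev.
make_passive_cell <- function(n_comp = 1, g_leak_nS = 1, erev = -70,
                              diam_um = 10, L_um = 20, ra = 100,
                              v_init = -70) {
  comps <- data.frame(
    name = paste0("c", seq_len(n_comp)),
    parent = c(NA_character_,
               if (n_comp > 1) paste0("c", seq_len(n_comp - 1))),
    L_um = L_um, diam_um = diam_um, sphere = FALSE,
    cm_specific = 1, ra = ra)
  channels <- data.frame(channel = "leak", comp = comps$name,
                         gbar_nS = g_leak_nS)
  cell_model("passive", comps, channels, passive_registry(),
             ca_shell = NULL, erev = list(leak = erev),
             temperature = 37, t_orig = 37, v_init = v_init)
}

cylinder_cm_nF <- function(diam_um, L_um, cm_specific = 1) {
  pi * (diam_um * 1e-4) * (L_um * 1e-4) * cm_specific * 1e3
}
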