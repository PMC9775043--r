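#!/usr/bin/env Rscript
# Step 2: characterize the single-cell models.
#
# Simulates the adapted granule cell (resting potential, f-I curve) and
# the Golgi cell (capacitance partition, autonomous pacemaking), and
# calibrates the mossy fiber-Golgi cell synapse to its -66 pA target.
# Writes results/02_single_cell.csv and results/02_grc_fi.csv.

suppressPackageStartupMessages(library(grcgain))
dir.create("results", showWarnings = FALSE)

grc <- build_grc()
rest <- simulate_cell(grc, 1000, record_every = 40L)
v_rest <- tail(rest$v, 1)
cat(sprintf("granule cell: %.2f pF total, rest %.2f mV after 1 s\n",
            total_capacitance(grc), v_rest))

fi <- do.call(rbind, lapply(c(4, 8, 15, 30) * 1e-3, function(b) {
  o <- simulate_cell(grc, 500, bias = b, record_every = 10L)
  data.frame(bias_pA = b * 1000, rate_Hz = length(o$spikes) / 0.5)
}))
write.csv(fi, "results/02_grc_fi.csv", row.names = FALSE)
cat("granule-cell f-I:",
    paste(sprintf("%g pA -> %g Hz", fi$bias_pA, fi$rate_Hz),
          collapse = ", "), "\n")

goc <- build_goc()
pace <- simulate_cell(goc, 3000, record_every = 40L)
isi <- diff(pace$spikes)
cat(sprintf("Golgi cell: %.1f pF total, pacemaking %.1f Hz (CV %.2f)\n",
            total_capacitance(goc),
            1000 / mean(isi), sd(isi) / mean(isi)))

cfg <- circuit_config(n_mf = 1, n_goc = 1, stochastic = FALSE)
circ <- wire_circuit(cfg)
peak <- mf_goc_epsc_peak(cfg, circ$mf_goc_scale)
cat(sprintf("mf-GoC synapse calibrated: scale %.2f, EPSC %.1f pA\n",
            circ$mf_goc_scale, peak))

write.csv(data.frame(
  quantity = c("grc_capacitance_pF", "grc_rest_mV", "goc_capacitance_pF",
               "goc_rate_Hz", "mf_goc_epsc_pA", "mf_goc_gmax_scale"),
  value = c(total_capacitance(grc), v_rest, total_capacitance(goc),
            1000 / mean(isi), peak, circ$mf_goc_scale)),
  "results/02_single_cell.csv", row.names = FALSE)
write_manifest(run_manifest("02_single_cell_models", list(), 1L,
                            c("results/02_single_cell.csv",
                              "results/02_grc_fi.csv")),
               "results/02_manifest.json")
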