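#!/usr/bin/env Rscript
# Step 1: validate the analysis pipelines on synthetic patch-clamp data.
#
# Generates voltage-clamp step transients, paired-pulse EPSC trains and
# pre/post plasticity data sets with known ground truth, runs the passive
# fit and the plasticity quantification, and tabulates how well each
# injected value is recovered. Writes results/01_passive_fits.csv and
# results/01_plasticity_outcomes.csv.

suppressPackageStartupMessages(library(grcgain))
dir.create("results", showWarnings = FALSE)
seed <- 20260929L

## Passive parameters: 25 synthetic cells drawn around the measured
## means (Cm 2.4 pF, Rm 2.3 GOhm, Rs 17.5 MOhm), 2% peak noise.
set.seed(seed)
cells <- data.frame(cm = rnorm(25, 2.4, 0.3), rm = rnorm(25, 2.3, 0.4),
                    rs = rnorm(25, 17.5, 1.3))
pass <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
  tt <- gen_vc_transient(cells$cm[i], cells$rm[i], cells$rs[i],
                         noise_frac = 0.02, seed = seed + i)
  fp <- fit_passive(tt$time, tt$current, 10)
  data.frame(cell = i, cm_true = cells$cm[i], cm_fit = fp$Cm_pF,
             rm_true = cells$rm[i], rm_fit = fp$Rm_GOhm,
             rs_true = cells$rs[i], rs_fit = fp$Rs_MOhm)
}))
write.csv(pass, "results/01_passive_fits.csv", row.names = FALSE)
cat(sprintf("passive recovery over %d cells: median |Cm err| %.1f%%, |Rm err| %.1f%%\n",
            nrow(pass),
            100 * median(abs(pass$cm_fit / pass$cm_true - 1)),
            100 * median(abs(pass$rm_fit / pass$rm_true - 1))))

## Plasticity quantification: 12 synthetic cells, half LTP, half LTD,
## 50 paired-pulse sweeps before and after the effect.
rows <- lapply(1:12, function(i) {
  mode <- if (i <= 6) "ltp" else "ltd"
  cfg <- synth_config(seed = seed + 1000L + i)
  post_cfg <- apply_plasticity_effect(cfg, mode)
  pre <- gen_epsc_train(c(20, 40), cfg, n_trials = 50,
                        seed = seed + 1000L + i)
  post <- gen_epsc_train(c(20, 40), post_cfg, n_trials = 50,
                         seed = seed + 1000L + i)
  # the EPSC amplitude is quantified on the first pulse; the second enters
  # through the paired-pulse ratio
  out <- plasticity_outcome(
    pre_epsc = epsc_peaks(pre, c(20, 40))[1, ],
    post_epsc = epsc_peaks(post, c(20, 40))[1, ],
    pre_ppr = ppr(pre, c(20, 40)), post_ppr = ppr(post, c(20, 40)))
  data.frame(cell = i, injected = mode, epsc_change = out$epsc_change,
             ppr_pre = out$ppr_pre, ppr_post = out$ppr_post,
             ppr_change = out$ppr_change, classified = out$classification)
})
outc <- do.call(rbind, rows)
write.csv(outc, "results/01_plasticity_outcomes.csv", row.names = FALSE)
cat(sprintf("plasticity classification: %d/%d correct; LTP EPSC %+0.1f%%, LTD %+0.1f%%\n",
            sum(outc$injected == outc$classified), nrow(outc),
            mean(outc$epsc_change[outc$injected == "ltp"]),
            mean(outc$epsc_change[outc$injected == "ltd"])))
write_manifest(run_manifest("01_synthetic_recordings", list(seed = seed),
                            seed,
                            c("results/01_passive_fits.csv",
                              "results/01_plasticity_outcomes.csv")),
               "results/01_manifest.json")
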