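#!/usr/bin/env Rscript
# Step 2 — quality control of the resting pair: temporal-SNR maps and
# between-subject comparison, receive-array noise-correlation summaries, and
# motion-trace checks against the 140 um / 0.6 deg bounds.

library(dyadfmri)

cfg <- list(seed = 20260101)
out <- "results/stages"
smry <- stage_tsnr("results/data/rest", out, cfg)
cat(sprintf("Mean tSNR: %s = %.1f, %s = %.1f (relative difference %.2f%%)\n",
            smry$table$subject[1], smry$table$mean_tsnr[1],
            smry$table$subject[2], smry$table$mean_tsnr[2],
            smry$relative_difference_pct))

nc <- stage_noisecorr("results/data/rest", out, cfg)
cat(sprintf("Noise correlation: intra-coil max %.1f%% / %.1f%%, inter-coil max %.2f%%\n",
            nc$summary$intra$coil1$max, nc$summary$intra$coil2$max,
            nc$summary$inter_coil_max))
cat(sprintf("Mean noise-level difference between coils: %.1f%%\n",
            nc$summary$noise_level_difference_pct))

mot <- stage_motion("results/data/rest", out, cfg)
cat(sprintf("Motion: %d/%d runs within bounds (max %.0f um, %.2f deg)\n",
            sum(mot$pass), nrow(mot), max(mot$max_translation_um),
            max(mot$max_rotation_deg)))
cat("QC tables under", out, "\n")
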