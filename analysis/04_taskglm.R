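#!/usr/bin/env Rscript
# Step 4 — block-design task analysis: per-run GLM (HRF-convolved condition
# regressors, fifth-order polynomials, low-frequency cosine drift, motion),
# paired transparent-vs-opaque contrast across runs, and the unpaired
# between-paradigm contrast on the stimulus coefficients.

library(dyadfmri)

cfg <- list(seed = 20260101)
res <- stage_glm("results/data/task_p1", "results/stages", cfg,
                 dataset_dir_p2 = "results/data/task_p2")

roi <- read_mask("results/data/task_p1/roi.nii.gz")
p <- res$paired
cat(sprintf("Paired contrast: df = %d, |t| >= %.2f\n", p$df, p$threshold))
cat(sprintf("  ROI mean effect %.2f (simulated beta 2 before smoothing); %.0f%% of ROI supra-threshold\n",
            mean(p$effect_map[roi$data]), 100 * mean(p$supra_mask[roi$data])))
u <- res$unpaired
cat(sprintf("Unpaired paradigm contrast: df = %d, |z| >= %.2f\n",
            u$df, u$threshold))
cat(sprintf("  ROI supra fraction %.2f, background supra fraction %.3f (nominal 0.05)\n",
            mean(u$supra_mask[roi$data]), mean(u$supra_mask[!roi$data])))
cat("Contrast maps under results/stages\n")
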