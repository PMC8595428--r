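#!/usr/bin/env Rscript
# Step 5 — aggregate every stage summary into results/stages/report.json.

library(dyadfmri)

rep <- pipeline_report("results/stages")
cat("Report sections:", paste(names(rep), collapse = ", "), "\n")
cat(sprintf("tSNR means: %s | motion all pass: %s | synchrony supra voxels: %d\n",
            paste(sprintf("%.1f", unlist(rep$tsnr$mean_tsnr)), collapse = "/"),
            rep$motion$all_pass, rep$synchrony$supra_voxels))
cat("Full report: results/stages/report.json\n")
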