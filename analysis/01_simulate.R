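#!/usr/bin/env Rscript
# Step 1 — generate the synthetic dual-subject datasets every later step
# analyses: a coupled "resting" pair (4 runs x 400 volumes, shared 0.01-0.1 Hz
# latent at rho = 0.3 in a central ROI) and two task paradigms (172-volume
# runs of the 17-block opaque/transparent design; paradigm 1 responds at
# beta = 2, paradigm 2 — the video-viewing control — at beta = 1).

library(dyadfmri)

seed <- 20260101
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

rest_cfg <- list(
  seed = seed,
  simulation = list(grid = list(dim = c(16, 16, 10)),
                    roi_size = c(6, 6, 4), rho = 0.3,
                    n_runs = 4, n_volumes = 400))
man <- simulate_dataset(rest_cfg, "results/data/rest")
cat(sprintf("Resting pair: %d files, %d runs x %d volumes, rho = %.2f\n",
            nrow(man$files), man$n_runs, man$n_volumes, man$rho))

task_cfg <- function(sd, beta) list(
  seed = sd,
  simulation = list(grid = list(dim = c(16, 16, 10)),
                    roi_size = c(6, 6, 4), rho = 0,
                    n_runs = 5, n_volumes = 172,
                    task = list(enabled = TRUE, beta = beta,
                                condition = "transparent")))
m1 <- simulate_dataset(task_cfg(seed + 1, 2), "results/data/task_p1")
m2 <- simulate_dataset(task_cfg(seed + 2, 1), "results/data/task_p2")
cat(sprintf("Task paradigms: %d + %d runs of %d volumes (beta 2 vs 1)\n",
            m1$n_runs, m2$n_runs, m1$n_volumes))
cat("Datasets written under results/data/\n")
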