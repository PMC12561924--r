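#!/usr/bin/env Rscript
# Simulate a posture study and write it as a trial store (one CSV log per
# trial plus a JSON manifest), exactly as a recorded study would arrive.
#
# The full study size is 27 subjects x 3 postures x 30 trials; the default
# here is a lighter 10 x 3 x 6 demonstration study so the whole analysis
# chain runs in a few minutes. Override with --subjects / --trials / --seed.

suppressPackageStartupMessages(library(spheregaze))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(f, d) { i <- which(args == f); if (length(i)) args[i + 1] else d }
n_sub <- as.integer(arg("--subjects", "10"))
n_tri <- as.integer(arg("--trials", "6"))
seed <- as.integer(arg("--seed", "1"))

cfg <- generator_config(n_subjects = n_sub, trials_per_posture = n_tri,
                        seed = seed)
store <- file.path("results", "store")
cat(sprintf("Simulating %d subjects x 3 postures x %d trials (seed %d)...\n",
            n_sub, n_tri, seed))
man <- generate_experiment(cfg, store)
cat(sprintf("Wrote %d trial logs and manifest.json under %s\n",
            nrow(man), store))
cat("Postures:", paste(sort(unique(man$posture)), collapse = ", "), "\n")
saveRDS(cfg, file.path("results", "config.rds"))
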