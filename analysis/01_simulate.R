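#!/usr/bin/env Rscript

# Step 1: generate the synthetic ventricular-surface dataset.
#
# Draws 20,000 cells from the calibrated EPE mixture plus neuroblast and
# microglia-like spike-ins, emulates the CD133 FACS split into PE/NC
# fractions, and writes the 10x-style matrix directory plus the run
# configuration under results/sim/.

suppressPackageStartupMessages(library(ependymap))

seed <- 101
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

profiles <- add_spike_ins(default_profiles(),
                          weights = c(neuroblast = 0.12, microglia_like = 0.08))
cfg <- sim_config(20000, profiles, seed = seed)
mat <- generate_expression(cfg)
mat <- generate_facs_split(mat, seed = seed + 1)

write_mtx_dir(mat, out_dir)
write_run_config(run_config(seed = seed, sim = cfg, out_dir = "results"),
                 file.path(out_dir, "run_config.yaml"))

cat("Simulated", nrow(mat$counts), "cells x", ncol(mat$counts), "genes\n")
cat("Subtype mix:\n")
print(round(prop.table(table(mat$truth_subtype)), 3))
cat("PE fraction:", round(mean(mat$facs_fraction == "PE"), 3), "\n")
cat("Wrote", out_dir, "\n")
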