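#!/usr/bin/env Rscript

# Step 2: quality control.
#
# Applies the standard cell/gene filters (creation gene count, gene
# prevalence, feature window, mitochondrial fraction) to the simulated
# dataset and reports what each rule removed.

suppressPackageStartupMessages(library(ependymap))

mat <- read_mtx_dir("results/sim")
res <- apply_qc(mat, qc_params())

print(res$report)
write_qc_report_json(res$report, "results/qc_report.json")
write_mtx_dir(res$matrix, "results/filtered")
cat("Wrote results/filtered and results/qc_report.json\n")
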