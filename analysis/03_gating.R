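#!/usr/bin/env Rscript

# Step 3: marker gating of the EPE compartment.
#
# Excludes microglia-like cells (not part of the ependymal surface proper)
# and neuroblasts, then: serial-depletion partition over
# Prom1 -> Flt1 -> Sox2 -> Pdgfrb -> Vim (plus the two published alternative
# orderings), marker marginals, pairwise co-expression conditionals, and the
# per-cell 12-class subtype labels.

suppressPackageStartupMessages(library(ependymap))

mat <- read_mtx_dir("results/filtered")
mat <- exclude_truth(mat, c("microglia_like", "neuroblast"))
cat("EPE cells after exclusion:", nrow(mat$counts), "\n")

scheme <- gating_scheme()
b <- binarize(mat, genes = unique(c(scheme$markers, "Actb", "Malat1")))

sd1 <- serial_depletion(b, scheme)
print(sd1$composition)
write.csv(sd1$composition, "results/serial_depletion.csv", row.names = FALSE)

for (ord in list(c("Prom1", "Sox2", "Vim", "Pdgfrb", "Flt1"),
                 c("Prom1", "Flt1", "Pdgfrb", "Sox2", "Vim"))) {
  alt <- serial_depletion(b, gating_scheme(ord))$composition
  cat("order", paste(ord, collapse = ">"), "-> remainder",
      round(alt$fraction[alt$bin == "undefined"], 4), "\n")
}

rates <- marker_positive_rates(b, c("Actb", "Malat1", "Vim", "Flt1", "Prom1",
                                    "Sox2", "Pdgfrb"))
print(rates)
write.csv(rates, "results/marker_rates.csv", row.names = FALSE)

pairs <- list(c("Flt1", "Prom1"), c("Pdgfrb", "Flt1"), c("Prom1", "Sox2"),
              c("Prom1", "Flt1"), c("Pdgfrb", "Sox2"), c("Vim", "Prom1"))
co <- coexpression(b, pairs)
print(co)
write.csv(co, "results/coexpression.csv", row.names = FALSE)

labels <- assign_subtypes(binarize(mat, genes = scheme$markers))
tab <- sort(table(labels), decreasing = TRUE)
print(round(prop.table(tab), 4))
write.csv(data.frame(cell_id = cell_ids(mat), subtype = as.character(labels)),
          "results/subtype_labels.csv", row.names = FALSE)
cat("Wrote serial_depletion / marker_rates / coexpression / subtype_labels\n")
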