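#!/usr/bin/env Rscript

# Step 4: layered-imaging quantification.
#
# Plants the shipped final composition into synthetic z-stack counts, under
# both idealised full detection and a layered detection profile in which
# CD133 (ciliary) is visible near the surface and SOX2 (nuclear) deeper.
# Compares the Added, Merged, Average 1 and Average 2 estimators.

suppressPackageStartupMessages(library(ependymap))

seed <- 104
planted <- final_composition_default()

z_full <- generate_zstack(planted, detection = NULL,
                          n_fields = 30, cells_per_field = 200, seed = seed)
q_full <- quantify_zstack(z_full)
write_zstack_csv(z_full, "results/zstack_full_detection.csv", seed = seed)

z_lay <- generate_zstack(planted, detection = layered_detection_example(),
                         n_fields = 30, cells_per_field = 200, seed = seed + 1)
q_lay <- quantify_zstack(z_lay)
write_zstack_csv(z_lay, "results/zstack_layered_detection.csv", seed = seed + 1)

show <- c("marker", "added", "merged", "average1", "average2_corrected",
          "average2_literal", "literal_flag")
cat("Full detection (CD133 planted at",
    sum(planted$fraction[planted$stratum == "CD133pos"]), "):\n")
print(q_full[q_full$marker == "CD133", show])
cat("\nLayered detection (ciliary CD133 fades below -1 um, so the Added\n")
cat("mean under-counts while the Merged projection recovers most cells):\n")
print(q_lay[q_lay$marker %in% c("CD133", "CD133pos_SOX2"), show])

write.csv(q_full, "results/zstack_quant_full.csv", row.names = FALSE)
write.csv(q_lay, "results/zstack_quant_layered.csv", row.names = FALSE)
cat("Wrote results/zstack_quant_{full,layered}.csv\n")
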