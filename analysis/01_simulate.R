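#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# The original orbital-disease cohort (three entities, 6/3/3 biopsies,
# multiplexed nCounter code set) is not public, so the analysis runs on a
# simulated stand-in with known ground truth: 300 endogenous genes, 30
# housekeeping genes, 6 positive and 8 negative control probes, lognormal
# lane effects, Poisson background, NB counts, and three gene sets spiked
# (ECM-receptor-like and adipocytokine-like up in the MALT-like group,
# cytokine-signaling-like up in the IgG4-like group).

library(countpath)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- reference_design(seed = 101)
panel <- simulate_panel(design)
sim <- simulate_counts(panel, design)

write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write_panel(panel, file.path(out, "panel.tsv"))
write_metadata(sim$metadata, file.path(out, "metadata.tsv"))
write_gmt(design_collection(design), file.path(out, "sets.gmt"))
jsonlite::write_json(
  list(enriched_sets = sim$truth$enriched_sets,
       affected_genes = sim$truth$affected_genes,
       lane_factors = as.list(round(sim$truth$lane_factors, 4))),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

message("wrote ", out, ": ", nrow(sim$counts$values), " probes x ",
        ncol(sim$counts$values), " lanes; spiked sets: ",
        paste(sim$truth$enriched_sets, collapse = ", "))
message("lane technical factors span [",
        round(min(sim$truth$lane_factors), 3), ", ",
        round(max(sim$truth$lane_factors), 3), "]")
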