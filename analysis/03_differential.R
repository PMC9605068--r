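#!/usr/bin/env Rscript
# Stage 3 — per-entity differential expression.
#
# One-vs-rest contrasts per entity: Shapiro-Wilk gates each gene into the
# pooled-variance t-test or the Mann-Whitney test, fold changes use the
# matching summary (means vs medians), and Benjamini-Hochberg runs across
# each table.

library(countpath)

panel <- read_panel("results/data/panel.tsv")
counts <- read_count_matrix("results/data/counts.tsv", panel)
metadata <- read_metadata("results/data/metadata.tsv")
cfg <- run_config(seed = 101)
norm <- normalize_pipeline(counts, panel, cfg)

dir.create("results/differential", showWarnings = FALSE, recursive = TRUE)
for (g in unique(metadata$group)) {
  tab <- suppressWarnings(
    differential_table(norm$counts, metadata, g, cfg))
  path <- file.path("results/differential",
                    paste0("differential_", g, ".tsv"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- tab[tab$fdr_p <= cfg$alpha, ]
  message(attr(tab, "contrast"), ": ", nrow(sig), " genes at FDR <= ",
          cfg$alpha, " (", sum(sig$log2fc > 0), " up, ",
          sum(sig$log2fc < 0), " down); tests used: ",
          sum(tab$test_used == "T_TEST"), " t / ",
          sum(tab$test_used == "WILCOXON"), " Wilcoxon")
  top <- head(sig[order(sig$fdr_p), ], 3)
  if (nrow(top) > 0) {
    message("  top genes: ",
            paste(sprintf("%s (log2FC %.2f, q %.2g)", top$gene, top$log2fc,
                          top$fdr_p), collapse = "; "))
  }
}
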