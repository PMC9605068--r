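Package: countpath
Title: NanoString nCounter Normalization, Differential Expression and
    Permutation Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An expression-to-pathway analysis workflow for NanoString
    nCounter count panels: technical normalization from positive control
    probes, negative-control background thresholding (mean plus two standard
    deviations) and subtraction, biological normalization from housekeeping
    reference genes, exclusion of genes not expressed above background by a
    one-sided Welch t-test, adaptive differential expression (Shapiro-Wilk
    gated t/Wilcoxon and ANOVA/Kruskal-Wallis with Benjamini-Hochberg FDR),
    a from-scratch permutation gene-set enrichment engine (enrichment score,
    normalized enrichment score, nominal p and NES-ratio FDR q), and
    per-pathway log2 fold-change projection into up/down/indifferent states.
    Includes a synthetic count-panel simulator with known ground truth (lane
    effects, additive background, overdispersed counts, spiked gene sets) so
    the whole chain is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
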