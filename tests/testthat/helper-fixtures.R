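# Tiny in-code fixtures shared across the suite.

tiny_panel <- function(n_endo = 3, n_hk = 2, n_pos = 2, n_neg = 2) {
  conc <- 128 / 4^(seq_len(n_pos) - 1)
  panel_definition(
    probe_name = c(sprintf("G%d", seq_len(n_endo)),
                   sprintf("HK%d", seq_len(n_hk)),
                   sprintf("POS_%s(%g)", LETTERS[seq_len(n_pos)], conc),
                   sprintf("NEG%d", seq_len(n_neg))),
    probe_class = rep(c("ENDOGENOUS", "HOUSEKEEPING", "POSITIVE", "NEGATIVE"),
                      times = c(n_endo, n_hk, n_pos, n_neg)),
    concentration = c(rep(NA, n_endo + n_hk), conc, rep(NA, n_neg)))
}

random_raw_matrix <- function(panel, n_samples = 4, seed = 1, max_count = 500) {
  set.seed(seed)
  # class-realistic levels: negatives at background, everything else higher
  lam <- ifelse(panel$probe_class == "NEGATIVE",
                runif(nrow(panel), 1, 10),
                runif(nrow(panel), 50, max_count))
  vals <- matrix(
    rpois(nrow(panel) * n_samples, lambda = lam),
    nrow = nrow(panel),
    dimnames = list(panel$probe_name, sprintf("S%d", seq_len(n_samples))))
  count_matrix(vals, stage = "RAW", panel = panel)
}

# naive step-by-step ES oracle, independent of the package implementation:
# literal walk over the ranked list accumulating hit/miss increments
naive_es <- function(scores, hit, weight) {
  N <- length(scores)
  w <- abs(scores)^weight
  n_r <- sum(w[hit])
  if (n_r == 0) {
    w <- rep(1, N)
    n_r <- sum(hit)
  }
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / n_r else -1 / (N - sum(hit))
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  # magnitude ties resolve to the positive side (package convention)
  if (hi >= -lo - 1e-12) hi else lo
}

# two-lane RCC fixture text
rcc_text <- function(sample_id, counts) {
  c("<Header>", "FileVersion,1.7", "SoftwareVersion,4.0", "</Header>",
    "<Sample_Attributes>", paste0("ID,", sample_id), "Owner,unit-test",
    "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", "FovCount,555", "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,ACC_%s,%d", counts$class, counts$name, counts$name,
            counts$count),
    "</Code_Summary>")
}

rcc_fixture_counts <- function(count_offset = 0) {
  data.frame(
    class = c(rep("Endogenous", 4), "Housekeeping", "Housekeeping",
              "Positive", "Positive", "Negative", "Negative"),
    name = c("GA", "GB", "GC", "GD", "HK1", "HK2",
             "POS_A(128)", "POS_B(32)", "NEG1", "NEG2"),
    count = c(120, 340, 55, 900, 400, 380, 5000, 1300, 3, 6) + count_offset,
    stringsAsFactors = FALSE)
}
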