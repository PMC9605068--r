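make_ranked <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  ord <- order(-scores, genes)
  out <- data.frame(gene = genes[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- "signal2noise"
  attr(out, "contrast") <- "test"
  class(out) <- c("ranked_list", "data.frame")
  out
}

test_that("gene ranking applies the signal-to-noise convention deterministically", {
  vals <- rbind(
    A = c(10, 10, 10, 5, 5, 5),       # sd 0 -> floored at 0.2*|mu|
    B = c(8, 12, 10, 3, 5, 7),
    C = c(5, 5, 5, 5, 5, 5))
  colnames(vals) <- sprintf("S%d", 1:6)
  cm <- count_matrix(vals, "BIO_NORMALIZED")
  md <- sample_metadata(colnames(vals), rep(c("g1", "g2"), each = 3))
  r <- rank_genes(cm, md, c("g1", "g2"))
  # gene A: (10-5) / (0.2*10 + 0.2*5) = 5/3
  expect_equal(r$score[r$gene == "A"], 5 / 3)
  expect_equal(r$score[r$gene == "C"], 0)
  # identical groups everywhere: all scores 0, gene-name order
  cm0 <- count_matrix(vals[, c(1:3, 1:3)] |>
                        `colnames<-`(sprintf("S%d", 1:6)), "BIO_NORMALIZED")
  r0 <- rank_genes(cm0, md, "g1")
  expect_equal(r0$score, rep(0, 3))
  expect_equal(r0$gene, c("A", "B", "C"))
  # permuting sample order within groups changes nothing
  cmp <- count_matrix(vals[, c(2, 3, 1, 6, 4, 5)], "BIO_NORMALIZED")
  expect_equal(rank_genes(cmp, md, c("g1", "g2"))$score, r$score)
})

test_that("enrichment score edge cases and hand-computed running sums", {
  # single-member set ranked first, weight 0: ES = 1
  r <- make_ranked(10:1)
  top_gene <- r$gene[1]
  es <- enrichment_score(r, top_gene, weight = 0)
  expect_equal(es$es, 1.0)
  expect_equal(es$leading_edge, top_gene)
  # ranked last: ES = -1
  es <- enrichment_score(r, r$gene[10], weight = 0)
  expect_equal(es$es, -1.0)
  # N = 4, |scores| = 1, members at ranks 1 and 3, weight 1:
  # running sum (0.5, 0, 0.5, 0) -> ES 0.5
  r4 <- make_ranked(c(1, 1, 1, 1), genes = c("a", "b", "c", "d"))
  es <- enrichment_score(r4, c("a", "c"), weight = 1)
  expect_equal(es$running_sum, c(0.5, 0, 0.5, 0))
  expect_equal(es$es, 0.5)
  # contract errors
  expect_error(enrichment_score(r4, letters[1:4]), "whole universe")
  expect_error(enrichment_score(r4, "zzz"), "no member")
  # zero-score hits under positive weight fall back to weight 0
  rz <- make_ranked(c(1, 0, 0, -1), genes = c("a", "b", "c", "d"))
  hit0 <- rz$gene[rz$score == 0][1]
  expect_warning(es <- enrichment_score(rz, hit0, weight = 1), "weight = 0")
  expect_true(abs(es$es) <= 1)
})

test_that("running sum telescopes to zero and ES stays within [-1, 1]", {
  set.seed(21)
  for (i in 1:50) {
    N <- sample(5:50, 1)
    scores <- round(rnorm(N), 3)
    r <- make_ranked(scores)
    k <- sample(seq_len(N - 1), 1)
    members <- sample(r$gene, k)
    w <- sample(c(0, 1, 1.5), 1)
    es <- suppressWarnings(enrichment_score(r, members, weight = w))
    expect_lte(abs(es$es), 1 + 1e-12)
    expect_equal(es$running_sum[N], 0, tolerance = 1e-12)
    expect_true(all(es$leading_edge %in% members))
  }
})

test_that("batch ES equals the naive walk oracle on random instances", {
  set.seed(77)
  for (i in 1:200) {
    N <- sample(4:50, 1)
    scores <- sort(round(rnorm(N) * 2, 3), decreasing = TRUE)
    k <- sample(seq_len(N - 1), 1)
    pos <- sort(sample.int(N, k))
    w <- sample(c(0, 1), 1)
    hit <- rep(FALSE, N); hit[pos] <- TRUE
    expected <- naive_es(scores, hit, w)
    got <- countpath:::es_batch(abs(scores)^w, matrix(pos, nrow = 1), N)
    expect_equal(got, expected, tolerance = 1e-12)
    # the exported walk agrees too
    r <- make_ranked(scores)
    got2 <- suppressWarnings(
      enrichment_score(r, r$gene[pos], weight = w)$es)
    expect_equal(got2, expected, tolerance = 1e-12)
  }
})

test_that("enrichment scores agree with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(99)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    r <- make_ranked(scores)
    k <- sample(2:(N - 2), 1)
    pos <- sort(sample.int(N, k))
    mine <- suppressWarnings(
      enrichment_score(r, r$gene[pos], weight = 1)$es)
    ref <- fgsea::calcGseaStat(setNames(r$score, r$gene), pos, gseaParam = 1,
                               scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("gene-set permutation nulls are reproducible and unbiased (exhaustive oracle)", {
  r <- make_ranked(c(2.0, 1.2, 0.7, 0.3, -0.1, -0.6, -1.1, -1.9))
  cfg <- run_config(seed = 1, n_permutations = 2000)
  set.seed(cfg$seed)
  null1 <- permutation_null(r, r$gene[c(1, 4, 6)], cfg)
  set.seed(cfg$seed)
  null2 <- permutation_null(r, r$gene[c(1, 4, 6)], cfg)
  expect_identical(null1, null2)
  expect_length(null1, 2000)
  expect_true(all(abs(null1) <= 1 + 1e-12))
  # exhaustive mean over all C(8,3) member sets
  combos <- combn(8, 3)
  all_es <- apply(combos, 2, function(pos) {
    hit <- rep(FALSE, 8); hit[pos] <- TRUE
    naive_es(r$score, hit, 1)
  })
  se <- sd(all_es) / sqrt(length(null1))
  expect_lt(abs(mean(null1) - mean(all_es)), 3 * se)
  expect_warning(
    {set.seed(1); permutation_null(r, r$gene[1:2],
                                   run_config(n_permutations = 50))},
    "unstable")
})

test_that("phenotype permutations fall back to exhaustive enumeration", {
  d <- simulation_design(n_endogenous = 20, n_housekeeping = 2,
                         groups = c(A = 3L, B = 3L), lane_factor_sd = 0,
                         background_mean = 0, seed = 12)
  panel <- simulate_panel(d)
  sim <- simulate_counts(panel, d)
  norm <- normalize_pipeline(sim$counts, panel, run_config())
  cfg <- run_config(seed = 2, n_permutations = 100,
                    permutation_mode = "PHENOTYPE")
  ranked <- rank_genes(norm$counts, sim$metadata, "A")
  expect_message(
    null <- permutation_null(ranked, gene_names(norm$counts)[1:5], cfg,
                             x = norm$counts, metadata = sim$metadata,
                             contrast = "A"),
    "enumerating exhaustively")
  expect_length(null, choose(6, 3))
  expect_true(all(abs(null) <= 1 + 1e-12))
})

test_that("set scoring recovers a spiked set and respects its invariants", {
  recovered <- vapply(1:20, function(s) {
    members <- sprintf("GENE_%04d", 1:30)
    spike <- list(name = "spiked", members = members, log2fc = 1,
                  affected_fraction = 0.6, target_group = "B")
    decoys <- lapply(1:5, function(i) sprintf("GENE_%04d", (50 + i * 30):(79 + i * 30)))
    names(decoys) <- sprintf("DECOY_%d", 1:5)
    d <- simulation_design(n_endogenous = 300, n_housekeeping = 10,
                           groups = c(A = 6L, B = 6L),
                           nb_dispersion = 0.1, lane_factor_sd = 0.2,
                           background_mean = 5,
                           spiked_sets = list(spike), extra_sets = decoys,
                           seed = 7000 + s)
    panel <- simulate_panel(d)
    sim <- simulate_counts(panel, d)
    norm <- normalize_pipeline(sim$counts, panel, run_config())
    col <- filter_gene_sets(design_collection(d), gene_names(norm$counts),
                            verbose = FALSE)
    res <- score_gene_sets(norm$counts, sim$metadata, "B", col,
                           run_config(seed = s, n_permutations = 1000))
    row <- res[res$set == "spiked", ]
    row$nes > 0 && !is.na(row$fdr_q) && row$fdr_q < 0.05
  }, logical(1))
  expect_gte(sum(recovered), 18)
})

test_that("scored tables are deterministic and ES flips under contrast reversal", {
  d <- simulation_design(n_endogenous = 60, n_housekeeping = 6,
                         groups = c(A = 4L, B = 4L), seed = 5,
                         extra_sets = list(s1 = sprintf("GENE_%04d", 1:12),
                                           s2 = sprintf("GENE_%04d", 20:45)))
  panel <- simulate_panel(d)
  sim <- simulate_counts(panel, d)
  norm <- normalize_pipeline(sim$counts, panel, run_config())
  col <- filter_gene_sets(gene_set_collection(d$extra_sets),
                          gene_names(norm$counts), verbose = FALSE)
  cfg <- run_config(seed = 3, n_permutations = 200)
  r1 <- score_gene_sets(norm$counts, sim$metadata, c("A", "B"), col, cfg)
  r2 <- score_gene_sets(norm$counts, sim$metadata, c("A", "B"), col, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$p_nominal > 0))
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0, na.rm = TRUE))
  # reversing the contrast flips the signal-to-noise ranking, hence ES sign
  r3 <- score_gene_sets(norm$counts, sim$metadata, c("B", "A"), col, cfg)
  for (s in r1$set) {
    expect_equal(r3$es[r3$set == s], -r1$es[r1$set == s], tolerance = 1e-9)
  }
  # leading edge is a subset of the measured members
  for (i in seq_len(nrow(r1))) {
    le <- strsplit(r1$leading_edge[i], ",", fixed = TRUE)[[1]]
    expect_true(all(le %in% col$sets[[r1$set[i]]]))
  }
})

test_that("nominal p-values are calibrated on null data", {
  # unspiked data, random sets: p_nominal < 0.05 should occur at ~5%
  frac <- vapply(1:10, function(s) {
    d <- simulation_design(n_endogenous = 150, n_housekeeping = 8,
                           groups = c(A = 6L, B = 6L),
                           nb_dispersion = 0.1, lane_factor_sd = 0.2,
                           background_mean = 5, seed = 9000 + s)
    panel <- simulate_panel(d)
    sim <- simulate_counts(panel, d)
    norm <- normalize_pipeline(sim$counts, panel, run_config())
    set.seed(s)
    sets <- lapply(1:25, function(i) {
      sample(gene_names(norm$counts), sample(10:30, 1))
    })
    names(sets) <- sprintf("NULLSET_%02d", 1:25)
    col <- gene_set_collection(sets)
    res <- score_gene_sets(norm$counts, sim$metadata, "B", col,
                           run_config(seed = s, n_permutations = 500))
    mean(res$p_nominal < 0.05, na.rm = TRUE)
  }, numeric(1))
  overall <- mean(frac)
  ci_half <- 2.576 * sqrt(0.05 * 0.95 / (10 * 25))
  expect_gt(overall, 0.05 - ci_half - 0.01)
  expect_lt(overall, 0.05 + ci_half + 0.01)
})
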