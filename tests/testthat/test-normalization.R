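test_that("technical factors follow the positive-sum formula", {
  p <- tiny_panel(n_endo = 2, n_hk = 1, n_pos = 2, n_neg = 2)
  vals <- matrix(c(10, 20, 5, 60, 40, 1, 2,    # lane 1, positives sum 100
                   30, 10, 8, 120, 80, 2, 1),  # lane 2, positives sum 200
                 ncol = 2,
                 dimnames = list(p$probe_name, c("L1", "L2")))
  raw <- count_matrix(vals, "RAW", panel = p)
  out <- technical_normalize(raw, p)
  expect_equal(unname(out$factors), c(1.5, 0.75))
  pos <- probes_of(p, "POSITIVE")
  expect_equal(unname(colSums(out$counts$values[pos, ])), c(150, 150))
  expect_equal(out$counts$stage, "TECH_NORMALIZED")

  # identical lanes: factors exactly 1, matrix unchanged
  same <- count_matrix(vals[, c(1, 1)] |>
                         `colnames<-`(c("L1", "L2")), "RAW", panel = p)
  out2 <- technical_normalize(same, p)
  expect_equal(unname(out2$factors), c(1, 1))
  expect_equal(out2$counts$values, same$values)

  # a lane with zero positive signal is named
  broken <- vals; broken[pos, 2] <- 0
  expect_error(
    technical_normalize(count_matrix(broken, "RAW", panel = p), p),
    "zero positive-probe signal: L2")
})

test_that("positive-probe sums equalize across lanes on random matrices", {
  p <- tiny_panel(n_endo = 5, n_hk = 2, n_pos = 3, n_neg = 3)
  pos <- probes_of(p, "POSITIVE")
  for (seed in 1:50) {
    raw <- random_raw_matrix(p, n_samples = 5, seed = seed)
    out <- technical_normalize(raw, p)
    sums <- colSums(out$counts$values[pos, ])
    expect_lt(diff(range(sums)) / mean(sums), 1e-9)
  }
})

test_that("background thresholds are the negative-control mean plus two SD", {
  p <- tiny_panel(n_endo = 1, n_hk = 1, n_pos = 2, n_neg = 3)
  vals <- matrix(c(50, 40, 100, 30, 1, 2, 3,
                   50, 40, 100, 30, 4, 4, 4),
                 ncol = 2, dimnames = list(p$probe_name, c("L1", "L2")))
  m <- count_matrix(vals, "RAW", panel = p)
  tn <- technical_normalize(m, p)  # identical lanes: unchanged
  thr <- background_threshold(tn$counts, p)
  expect_equal(unname(thr[1]), 4)  # mean 2, sd 1 -> 2 + 2*1
  expect_equal(unname(thr[2]), 4)  # zero variance: threshold = c

  # oracle equivalence on random lanes: two-pass mean/SD computed by hand
  set.seed(9)
  for (i in 1:100) {
    negs <- matrix(rpois(8, 10), nrow = 4,
                   dimnames = list(sprintf("NEG%d", 1:4), c("A", "B")))
    full <- rbind(matrix(c(5, 5), nrow = 1, dimnames = list("G1", NULL)),
                  matrix(c(60, 60, 20, 20), nrow = 2,
                         dimnames = list(c("POS_A(128)", "POS_B(32)"), NULL)),
                  negs)
    colnames(full) <- c("A", "B")
    pan <- panel_definition(rownames(full),
                            c("ENDOGENOUS", "POSITIVE", "POSITIVE",
                              rep("NEGATIVE", 4)),
                            c(NA, 128, 32, rep(NA, 4)))
    cm <- count_matrix(full, "TECH_NORMALIZED")
    thr <- background_threshold(cm, pan)
    for (j in 1:2) {
      v <- negs[, j]
      mu <- sum(v) / length(v)
      s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
      expect_equal(unname(thr[j]), mu + 2 * s)
    }
  }
})

test_that("background subtraction clamps at zero and spares control probes", {
  p <- tiny_panel(n_endo = 2, n_hk = 1, n_pos = 2, n_neg = 2)
  vals <- matrix(c(10, 3, 8, 60, 20, 2, 2), ncol = 1,
                 dimnames = list(p$probe_name, "L1"))
  m <- count_matrix(vals, "TECH_NORMALIZED")
  out <- subtract_background(m, p, c(L1 = 4))
  expect_equal(unname(out$values[, 1]), c(6, 0, 4, 60, 20, 2, 2))
  expect_equal(out$stage, "BACKGROUND_SUBTRACTED")
  # zero thresholds leave the matrix unchanged
  out0 <- subtract_background(m, p, c(L1 = 0))
  expect_equal(out0$values, m$values)
})

test_that("housekeeping factors equalize geometric means across lanes", {
  p <- tiny_panel(n_endo = 1, n_hk = 2, n_pos = 2, n_neg = 2)
  vals <- matrix(c(5, 20, 5, 60, 20, 1, 1,    # hk geomean 10
                   5, 80, 20, 60, 20, 1, 1),  # hk geomean 40
                 ncol = 2, dimnames = list(p$probe_name, c("L1", "L2")))
  m <- count_matrix(vals, "BACKGROUND_SUBTRACTED")
  out <- biological_normalize(m, p)
  expect_equal(unname(out$factors), c(2.5, 0.625))
  expect_equal(out$counts$stage, "BIO_NORMALIZED")

  # random matrices: post-normalization geomeans equal within 1e-9 relative
  hk <- probes_of(p, "HOUSEKEEPING")
  for (seed in 1:30) {
    raw <- random_raw_matrix(tiny_panel(n_endo = 1, n_hk = 2), 4, seed)
    m <- count_matrix(raw$values + 1, "BACKGROUND_SUBTRACTED")
    out <- biological_normalize(m, p)
    gm <- apply(out$counts$values[hk, ], 2, function(v) exp(mean(log(v))))
    expect_lt(diff(range(gm)) / mean(gm), 1e-9)
  }

  # all housekeeping zero somewhere -> error advising inspection
  dead <- vals; dead[hk, 1] <- 0
  expect_error(
    biological_normalize(count_matrix(dead, "BACKGROUND_SUBTRACTED"), p),
    "background subtraction")
})

test_that("the expression filter keeps genes above background (frozen Welch oracle)", {
  pan <- panel_definition(
    c("G1", "G2", "POS_A(128)", "POS_B(32)", "NEG1", "NEG2", "NEG3"),
    c("ENDOGENOUS", "ENDOGENOUS", "POSITIVE", "POSITIVE",
      rep("NEGATIVE", 3)),
    c(NA, NA, 128, 32, NA, NA, NA))
  # gene G1 = {100,110,90,105}; pooled negatives over the 4 lanes =
  # {1,2,1, 2,3,2, 3,2,3, 2,1,2}
  vals <- matrix(c(100, 0, 50, 50, 1, 2, 1,
                   110, 0, 50, 50, 2, 3, 2,
                   90,  0, 50, 50, 3, 2, 3,
                   105, 0, 50, 50, 2, 1, 2), ncol = 4,
                 dimnames = list(pan$probe_name, c("A", "B", "C", "D")))
  m4 <- count_matrix(vals, "BIO_NORMALIZED")
  flt4 <- suppressWarnings(background_filter(m4, pan, alpha = 0.05))
  # frozen oracle: scipy.stats.ttest_ind(gene, negatives, equal_var=False,
  # alternative="greater")
  expect_equal(unname(flt4$p_values[["G1"]]), 8.463845262152869e-05,
               tolerance = 1e-10)
  expect_true("G1" %in% flt4$retained)       # far above background
  expect_false("G2" %in% flt4$retained)      # all-zero gene: one-sided miss
})

test_that("filter type-I rate is near alpha for genes at background level", {
  # genes drawn from the same Poisson as the negatives are retained ~5%
  set.seed(31)
  n_genes <- 1000
  n_lane <- 6
  retained <- logical(n_genes)
  negs <- matrix(rpois(8 * n_lane, 10), nrow = 8)
  pooled <- as.vector(negs)
  for (g in seq_len(n_genes)) {
    v <- rpois(n_lane, 10)
    p <- tryCatch(t.test(v, pooled, alternative = "greater")$p.value,
                  error = function(e) 1)
    retained[g] <- p < 0.05
  }
  expect_lt(mean(retained), 0.10)  # one-sided 5% nominal, guard band
})

test_that("the full chain removes lane effects and is idempotent on factors", {
  d <- simulation_design(n_endogenous = 60, n_housekeeping = 8,
                         groups = c(A = 4L, B = 4L),
                         lane_factor_sd = 0.4, background_mean = 4,
                         nb_dispersion = 0.05, seed = 17)
  panel <- simulate_panel(d)
  improved <- vapply(1:20, function(seed) {
    di <- simulation_design(n_endogenous = 60, n_housekeeping = 8,
                            groups = c(A = 4L, B = 4L),
                            lane_factor_sd = 0.4, background_mean = 4,
                            nb_dispersion = 0.05, seed = seed)
    sim <- simulate_counts(panel, di)
    hk <- probes_of(panel, "HOUSEKEEPING")
    cv <- function(x) sd(x) / mean(x)
    before <- cv(colSums(sim$counts$values[hk, ]))
    norm <- normalize_pipeline(sim$counts, panel, run_config())
    tn <- technical_normalize(sim$counts, panel)
    thr <- background_threshold(tn$counts, panel)
    sub <- subtract_background(tn$counts, panel, thr)
    bio <- biological_normalize(sub, panel)
    after <- cv(colSums(bio$counts$values[hk, ]))
    after < before
  }, logical(1))
  expect_gte(sum(improved), 19)

  # idempotence: re-running the chain on its own output gives factors ~ 1
  sim <- simulate_counts(panel, d)
  norm <- normalize_pipeline(sim$counts, panel, run_config())
  tn <- technical_normalize(sim$counts, panel)
  thr <- background_threshold(tn$counts, panel)
  sub <- subtract_background(tn$counts, panel, thr)
  bio <- biological_normalize(sub, panel)
  rerun <- count_matrix(round(bio$counts$values), "RAW")
  tn2 <- technical_normalize(rerun, panel)
  expect_equal(unname(tn2$factors), rep(1, 8), tolerance = 1e-2)
})

test_that("pipeline output partitions genes and carries no control probes", {
  d <- simulation_design(n_endogenous = 40, n_housekeeping = 5,
                         groups = c(A = 3L, B = 3L), seed = 23)
  panel <- simulate_panel(d)
  sim <- simulate_counts(panel, d)
  out <- normalize_pipeline(sim$counts, panel, run_config())
  endo <- probes_of(panel, "ENDOGENOUS")
  expect_setequal(c(out$report$retained_genes, out$report$excluded_genes$gene),
                  endo)
  expect_length(intersect(out$report$retained_genes,
                          out$report$excluded_genes$gene), 0)
  expect_true(all(gene_names(out$counts) %in% endo))
  expect_true(all(out$report$technical_factors > 0))
  expect_true(all(out$report$housekeeping_factors > 0))
})

test_that("each normalization step is monotone within a lane", {
  d <- simulation_design(n_endogenous = 30, n_housekeeping = 4,
                         groups = c(A = 3L, B = 3L),
                         lane_factor_sd = 0.3, background_mean = 6, seed = 41)
  panel <- simulate_panel(d)
  sim <- simulate_counts(panel, d)
  tn <- technical_normalize(sim$counts, panel)
  thr <- background_threshold(tn$counts, panel)
  sub <- subtract_background(tn$counts, panel, thr)
  bio <- biological_normalize(sub, panel)
  endo <- probes_of(panel, "ENDOGENOUS")
  for (j in seq_len(ncol(sim$counts$values))) {
    before <- sim$counts$values[endo, j]
    after <- bio$counts$values[endo, j]
    ord <- order(before)
    expect_true(all(diff(after[ord]) >= -1e-12))
  }
})
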