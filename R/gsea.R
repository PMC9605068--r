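#' Rank genes for enrichment analysis
#'
#' Scores every gene of the matrix on a group-vs-rest (or pairwise) contrast
#' and sorts descending. `signal2noise` is
#' `(mu_A - mu_B) / (sd_A + sd_B)` with each standard deviation floored at
#' `max(0.2 * |mu|, 0.2)` — the convention of the GSEA method family, which
#' keeps low-variance genes from dominating. `log2_median_ratio` is the
#' non-parametric alternative: the log2 ratio of group medians with a
#' pseudocount. Ties in the score are broken by gene name (ascending) so the
#' ranking is deterministic.
#'
#' @param x a `count_matrix`.
#' @param metadata a `sample_metadata`.
#' @param contrast one group label (vs rest) or two labels (pairwise).
#' @param metric `"signal2noise"` (default) or `"log2_median_ratio"`.
#' @param pseudocount used by the median-ratio metric (default 1).
#' @return a `ranked_list` data frame (`gene`, `score`) sorted descending,
#'   with attributes `metric` and `contrast`.
#' @export
rank_genes <- function(x, metadata, contrast,
                       metric = c("signal2noise", "log2_median_ratio"),
                       pseudocount = 1) {
  metric <- match.arg(metric)
  groups <- check_metadata(x, metadata)
  sel <- resolve_contrast(groups, contrast)
  A <- x$values[, sel$a, drop = FALSE]
  B <- x$values[, sel$b, drop = FALSE]
  score <- if (metric == "signal2noise") {
    mu_a <- rowMeans(A); mu_b <- rowMeans(B)
    sd_a <- apply(A, 1, stats::sd); sd_b <- apply(B, 1, stats::sd)
    sd_a <- pmax(sd_a, 0.2 * abs(mu_a), 0.2)
    sd_b <- pmax(sd_b, 0.2 * abs(mu_b), 0.2)
    (mu_a - mu_b) / (sd_a + sd_b)
  } else {
    log2((apply(A, 1, stats::median) + pseudocount) /
         (apply(B, 1, stats::median) + pseudocount))
  }
  ord <- order(-score, gene_names(x))
  out <- data.frame(gene = gene_names(x)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "contrast") <- sel$label
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Enrichment score of a gene set on a ranked list
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic: walking the ranked
#' list, a hit (set member) adds `|score|^weight / N_R` (`N_R` = the sum of
#' `|score|^weight` over hits) and a miss subtracts `1 / (N - N_h)`. The
#' enrichment score is the deviation of maximal absolute value (sign kept;
#' a tie in magnitude resolves to the positive side). The leading edge is the
#' hits at or before the extremum for positive ES, and at or after it for
#' negative ES.
#'
#' When every hit has score 0 and `weight > 0`, the weighted increments are
#' undefined; the statistic falls back to `weight = 0` with a warning.
#'
#' @param ranked a `ranked_list`.
#' @param members character vector of set members; the intersection with the
#'   ranked universe must be non-empty and smaller than the universe.
#' @param weight non-negative exponent on |score| (default 1).
#' @return list with `es`, `running_sum` (length N), and `leading_edge`.
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  hit <- ranked$gene %in% members
  N <- length(hit)
  n_hit <- sum(hit)
  if (n_hit == 0) stop2("gene set has no member in the ranked universe")
  if (n_hit == N) stop2("gene set equals the whole universe; ES undefined")
  w <- abs(ranked$score) ^ weight
  n_r <- sum(w[hit])
  if (n_r == 0 && weight > 0) {
    warning("all hit scores are zero; falling back to weight = 0",
            call. = FALSE)
    w <- rep(1, N)
    n_r <- n_hit
  }
  if (weight == 0) {
    w <- rep(1, N)
    n_r <- n_hit
  }
  steps <- ifelse(hit, w / n_r, -1 / (N - n_hit))
  running <- cumsum(steps)
  i_max <- which.max(running)
  i_min <- which.min(running)
  # magnitude ties (possible with weight-0 rational steps) resolve positive
  es <- if (running[i_max] >= -running[i_min] - 1e-12) {
    running[i_max]
  } else {
    running[i_min]
  }
  leading <- if (es >= 0) {
    ranked$gene[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    idx <- seq(i_min, N)
    # extremum of a negative ES is the low point just before a hit run begins;
    # the hits from that point on drive the depletion
    ranked$gene[idx][hit[idx]]
  }
  list(es = es, running_sum = running, leading_edge = leading)
}

# Batch ES over permuted member positions (one row of `pos` per permutation,
# columns = sorted hit positions in 1..N). Evaluates the running sum only at
# hit boundaries: right after hit i the sum is P_i/NR - (pos_i - i)/(N - k),
# just before it P_{i-1}/NR - (pos_i - i)/(N - k); maxima/minima of the walk
# occur only there (or at 0). Exact match to the step-by-step walk is
# asserted in the tests.
es_batch <- function(abs_w, pos, N) {
  k <- ncol(pos)
  W <- matrix(abs_w[pos], nrow = nrow(pos), ncol = k)
  NR <- rowSums(W)
  zero_nr <- NR == 0
  if (any(zero_nr)) {  # weight-0 fallback, mirrored from enrichment_score
    W[zero_nr, ] <- 1
    NR[zero_nr] <- k
  }
  U <- upper.tri(matrix(0, k, k), diag = TRUE)
  Pcum <- W %*% U
  miss <- sweep(pos, 2, seq_len(k), `-`) / (N - k)
  after <- Pcum / NR - miss
  before <- (Pcum - W) / NR - miss
  maxdev <- pmax(do.call(pmax, c(asplit(after, 2), list(0))), 0)
  mindev <- pmin(do.call(pmin, c(asplit(before, 2), list(0))), 0)
  as.numeric(ifelse(maxdev >= -mindev - 1e-12, maxdev, mindev))
}

#' Permutation null distribution of the enrichment score
#'
#' `GENE_SET` mode draws random member sets of the observed size from the
#' ranked universe and recomputes the ES on the fixed ranking. `PHENOTYPE`
#' mode shuffles the group labels, re-ranks, and recomputes; when fewer
#' distinct label assignments exist than permutations requested, all of them
#' are enumerated instead (with a message). Reproducible under the caller's
#' RNG state; [score_gene_sets()] seeds it from the config.
#'
#' @param ranked a `ranked_list` (the observed ranking).
#' @param members gene-set members.
#' @param config a `run_config` (n_permutations, permutation_mode,
#'   gsea_weight; fewer than 100 permutations triggers a warning — the FDR
#'   becomes unstable).
#' @param x,metadata,contrast required for `PHENOTYPE` mode only: the data
#'   and contrast to re-rank under shuffled labels.
#' @return numeric vector of permuted enrichment scores (all in [-1, 1]).
#' @export
permutation_null <- function(ranked, members, config,
                             x = NULL, metadata = NULL, contrast = NULL) {
  if (config$n_permutations < 100) {
    warning("fewer than 100 permutations: FDR estimates will be unstable",
            call. = FALSE)
  }
  N <- nrow(ranked)
  k <- sum(ranked$gene %in% members)
  if (k == 0 || k == N) stop2("set size must be in [1, N-1] after intersection")
  if (config$permutation_mode == "GENE_SET") {
    abs_w <- abs(ranked$score) ^ config$gsea_weight
    pos <- t(vapply(seq_len(config$n_permutations),
                    function(i) sort.int(sample.int(N, k)),
                    integer(k)))
    if (k == 1) pos <- matrix(pos, ncol = 1)
    es_batch(abs_w, pos, N)
  } else {
    if (is.null(x) || is.null(metadata) || is.null(contrast)) {
      stop2("PHENOTYPE mode needs the count matrix, metadata and contrast")
    }
    groups <- check_metadata(x, metadata)
    sel <- resolve_contrast(groups, contrast)
    n <- length(groups)
    n_a <- length(sel$a)
    n_distinct <- choose(n, n_a)
    assignments <- if (n_distinct <= config$n_permutations) {
      message("only ", n_distinct, " distinct label assignments; ",
              "enumerating exhaustively")
      utils::combn(n, n_a, simplify = FALSE)
    } else {
      lapply(seq_len(config$n_permutations),
             function(i) sample.int(n, n_a))
    }
    vapply(assignments, function(idx) {
      lab <- rep("rest__", n)
      lab[idx] <- "target__"
      md <- sample_metadata(sample_names(x), lab)
      rr <- rank_genes(x, md, "target__",
                       metric = attr(ranked, "metric"))
      enrichment_score(rr, members, weight = config$gsea_weight)$es
    }, numeric(1))
  }
}

#' Score a gene-set collection by permutation GSEA
#'
#' For each set: the enrichment score on the observed ranking; the normalized
#' enrichment score `NES = ES / mean(|permuted ES| of the same sign)`
#' (positive and negative sides normalized separately, so sets of different
#' sizes are comparable); the nominal p-value by the add-one permutation
#' estimator `(1 + #{same-sign |permuted ES| >= |ES|}) / (1 + #same-sign)`
#' (never exactly 0); and the FDR q by the NES-ratio method — the fraction of
#' all (pooled, normalized) permuted NES at or beyond the observed NES over
#' the fraction of observed NES at or beyond it, same sign, capped at 1 and
#' monotonized step-up within each sign. `config$gsea_fdr = "bh"` instead
#' applies Benjamini-Hochberg to the nominal p-values.
#'
#' @param x a `count_matrix` (normalized and background-filtered).
#' @param metadata a `sample_metadata`.
#' @param contrast one group (vs rest) or two groups.
#' @param collection a `gene_set_collection`, already size-filtered against
#'   the matrix's gene universe ([filter_gene_sets()]).
#' @param config a `run_config`.
#' @return a `gsea_result` data frame sorted by `fdr_q` then `|nes|`
#'   descending: `set`, `size_used`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `leading_edge` (comma-joined); attributes `contrast` and `ranking`.
#' @export
score_gene_sets <- function(x, metadata, contrast, collection,
                            config = run_config()) {
  set.seed(config$seed)
  ranked <- rank_genes(x, metadata, contrast, metric = config$metric,
                       pseudocount = config$pseudocount)
  sets <- collection$sets
  obs <- lapply(sets, function(m) {
    enrichment_score(ranked, m, weight = config$gsea_weight)
  })
  perms <- lapply(sets, function(m) {
    permutation_null(ranked, m, config,
                     x = x, metadata = metadata, contrast = contrast)
  })
  es <- vapply(obs, `[[`, numeric(1), "es")
  nes <- rep(NA_real_, length(sets))
  p_nom <- rep(NA_real_, length(sets))
  perm_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    pe <- perms[[i]]
    pos_mean <- mean(pe[pe > 0])
    neg_mean <- mean(abs(pe[pe < 0]))
    same <- if (es[i] >= 0) pe[pe >= 0] else pe[pe <= 0]
    if (length(same) == 0 ||
        (es[i] >= 0 && !is.finite(pos_mean)) ||
        (es[i] < 0 && !is.finite(neg_mean))) {
      warning("set '", names(sets)[i], "': no same-sign permutation; ",
              "NES undefined", call. = FALSE)
      next
    }
    nes[i] <- if (es[i] >= 0) es[i] / pos_mean else es[i] / neg_mean
    p_nom[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    pn <- rep(NA_real_, length(pe))
    if (is.finite(pos_mean)) pn[pe > 0] <- pe[pe > 0] / pos_mean
    if (is.finite(neg_mean)) pn[pe < 0] <- pe[pe < 0] / neg_mean
    pn[pe == 0] <- 0
    perm_nes[[i]] <- pn[!is.na(pn)]
  }
  fdr_q <- if (config$gsea_fdr == "bh") {
    ok <- !is.na(p_nom)
    q <- rep(NA_real_, length(p_nom))
    q[ok] <- bh_fdr(p_nom[ok])
    q
  } else {
    nes_ratio_fdr(nes, unlist(perm_nes))
  }
  out <- data.frame(
    set = names(sets),
    size_used = vapply(sets, function(m) sum(ranked$gene %in% m), integer(1)),
    es = unname(es),
    nes = nes,
    p_nominal = p_nom,
    fdr_q = fdr_q,
    leading_edge = vapply(obs, function(o) {
      paste(o$leading_edge, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$fdr_q, -abs(out$nes)), ]
  rownames(out) <- NULL
  attr(out, "contrast") <- attr(ranked, "contrast")
  attr(out, "ranking") <- ranked
  class(out) <- c("gsea_result", "data.frame")
  out
}

# NES-ratio FDR: for each observed NES, the tail fraction of the pooled
# permuted NES over the tail fraction of the observed NES, same sign, capped
# at 1, then monotonized step-up (q non-decreasing as |NES| shrinks) within
# each sign.
nes_ratio_fdr <- function(nes, pooled) {
  q <- rep(NA_real_, length(nes))
  ok <- which(!is.na(nes))
  for (i in ok) {
    if (nes[i] >= 0) {
      denom_pool <- sum(pooled >= 0)
      num <- if (denom_pool > 0) sum(pooled >= nes[i]) / denom_pool else 0
      den <- sum(nes[ok] >= nes[i]) / sum(nes[ok] >= 0)
    } else {
      denom_pool <- sum(pooled < 0)
      num <- if (denom_pool > 0) sum(pooled <= nes[i]) / denom_pool else 0
      den <- sum(nes[ok] <= nes[i]) / sum(nes[ok] < 0)
    }
    q[i] <- min(1, num / den)
  }
  for (side in list(ok[nes[ok] >= 0], ok[nes[ok] < 0])) {
    if (length(side) < 2) next
    ord <- side[order(-abs(nes[side]))]
    # step-up: each set's q is the smallest raw q among itself and every
    # less-extreme set on its side
    q[ord] <- rev(cummin(rev(q[ord])))
  }
  q
}
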