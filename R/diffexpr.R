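#' Shapiro-Wilk normality gate
#'
#' Decides the parametric vs non-parametric branch per group: a group is
#' flagged normal iff its Shapiro-Wilk p-value is at least `alpha`. Groups
#' that cannot be tested (fewer than 3 values, or constant values) are flagged
#' non-normal with a warning, never an error.
#'
#' @param values_by_group named list of numeric vectors.
#' @param alpha gate level (default 0.05).
#' @return named logical vector, `TRUE` = treat as normal.
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  vapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    if (length(v) < 3) {
      warning("group '", g, "': fewer than 3 values, flagged non-normal",
              call. = FALSE)
      return(FALSE)
    }
    if (stats::sd(v) == 0) {
      warning("group '", g, "': constant values, flagged non-normal",
              call. = FALSE)
      return(FALSE)
    }
    stats::shapiro.test(v)$p.value >= alpha
  }, logical(1))
}

#' Adaptive two-group test
#'
#' Parametric branch (all gate flags TRUE): two-sided pooled-variance Student
#' t-test with a 95% confidence interval for the mean difference. Otherwise:
#' two-sided Wilcoxon/Mann-Whitney rank-sum test, exact when the smaller group
#' has at most 8 values and there are no ties, normal approximation with tie
#' and continuity correction otherwise. Completely tied data yield p = 1.
#'
#' @param a,b numeric vectors, each length >= 2.
#' @param gate logical vector from [normality_gate()] on the two groups.
#' @return list with `test_used` (`"T_TEST"` or `"WILCOXON"`), `p`, and `ci`
#'   (length-2 numeric for the parametric branch, `NULL` otherwise).
#' @export
two_group_test <- function(a, b, gate) {
  if (length(a) < 2 || length(b) < 2) stop2("each group needs >= 2 values")
  parametric <- all(gate)
  if (parametric) {
    fit <- tryCatch(stats::t.test(a, b, var.equal = TRUE, conf.level = 0.95),
                    error = function(e) NULL)
    if (is.null(fit)) {  # both groups constant and equal
      return(list(test_used = "T_TEST", p = 1, ci = c(0, 0)))
    }
    list(test_used = "T_TEST", p = fit$p.value, ci = unname(fit$conf.int))
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    if (ties && stats::sd(c(a, b)) == 0) {
      return(list(test_used = "WILCOXON", p = 1, ci = NULL))
    }
    exact <- !ties && min(length(a), length(b)) <= 8
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    list(test_used = "WILCOXON", p = p, ci = NULL)
  }
}

#' Adaptive multi-group test
#'
#' One-way ANOVA (equal-variance F test) when every group passes the
#' normality gate, Kruskal-Wallis with tie correction otherwise.
#'
#' @param values_by_group named list of >= 3 numeric vectors, each length
#'   >= 2.
#' @param gate logical vector from [normality_gate()].
#' @return list with `test_used` (`"ANOVA"` or `"KRUSKAL_WALLIS"`),
#'   `statistic` (F or H) and `p`.
#' @export
multi_group_test <- function(values_by_group, gate) {
  if (length(values_by_group) < 3) stop2("need >= 3 groups")
  if (any(lengths(values_by_group) < 2)) stop2("each group needs >= 2 values")
  all_vals <- unlist(values_by_group, use.names = FALSE)
  if (stats::sd(all_vals) == 0) {
    return(list(test_used = if (all(gate)) "ANOVA" else "KRUSKAL_WALLIS",
                statistic = 0, p = 1))
  }
  if (all(gate)) {
    fit <- stats::oneway.test(
      values ~ group,
      data = data.frame(
        values = all_vals,
        group = factor(rep(names(values_by_group),
                           lengths(values_by_group)))),
      var.equal = TRUE)
    list(test_used = "ANOVA", statistic = unname(fit$statistic),
         p = fit$p.value)
  } else {
    fit <- stats::kruskal.test(values_by_group)
    list(test_used = "KRUSKAL_WALLIS", statistic = unname(fit$statistic),
         p = fit$p.value)
  }
}

#' Log2 fold change between group summaries
#'
#' `log2((m_a + pseudocount) / (m_b + pseudocount))` with `m` the group mean
#' on the parametric branch and the group median on the non-parametric branch.
#' The pseudocount (default 1) guards the zeros created by background
#' subtraction.
#'
#' @param a,b numeric vectors of non-negative expression values.
#' @param parametric use means (`TRUE`) or medians (`FALSE`).
#' @param pseudocount non-negative real added to both summaries.
#' @return the signed log2 fold change (a over b).
#' @export
log2_fold_change <- function(a, b, parametric = TRUE, pseudocount = 1) {
  m <- if (parametric) mean else stats::median
  log2((m(a) + pseudocount) / (m(b) + pseudocount))
}

#' Pearson and Spearman correlation with tests
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`;
#'   all `NA` with a warning when either input has zero variance.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop2("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) FDR adjustment
#'
#' Step-up adjusted p-values, returned in input order; never smaller than the
#' raw p-value, never above 1.
#'
#' @param p_values numeric vector in [0, 1].
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop2("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

# resolve a contrast into the two sample index sets and a printable label
resolve_contrast <- function(groups, contrast) {
  if (length(contrast) == 1) {
    if (!contrast %in% groups) stop2("unknown contrast group '", contrast, "'")
    if (length(unique(groups)) < 2) stop2("need >= 2 groups for a contrast")
    list(a = which(groups == contrast), b = which(groups != contrast),
         label = paste0(contrast, "_vs_rest"))
  } else if (length(contrast) == 2) {
    missing <- setdiff(contrast, groups)
    if (length(missing) > 0) {
      stop2("unknown contrast group(s): ", paste(missing, collapse = ", "))
    }
    list(a = which(groups == contrast[1]), b = which(groups == contrast[2]),
         label = paste0(contrast[1], "_vs_", contrast[2]))
  } else {
    stop2("contrast must be one group (one-vs-rest) or two groups (pairwise)")
  }
}

#' Per-gene differential expression table
#'
#' For each gene of a normalized, background-filtered matrix: the Shapiro-Wilk
#' gate decides the test (t-test vs Wilcoxon), the matching summary decides
#' the log2 fold change (means vs medians), and Benjamini-Hochberg adjustment
#' runs across all genes of the table. Confidence intervals (mean difference,
#' normalized-count scale) are reported for the parametric branch only.
#'
#' @param x a BIO_NORMALIZED `count_matrix`.
#' @param metadata a `sample_metadata` covering the matrix.
#' @param contrast one group label (that group vs all others) or two labels
#'   (pairwise); the fold change is first-over-second.
#' @param config a `run_config` (alpha, fdr_method, pseudocount).
#' @return a `differential_result` data frame: `gene`, `test_used`, `log2fc`,
#'   `p_value`, `fdr_p`, `ci_low`, `ci_high`, `normal_a`, `normal_b`, with
#'   attribute `contrast`.
#' @export
differential_table <- function(x, metadata, contrast, config = run_config()) {
  check_stage(x, "BIO_NORMALIZED")
  groups <- check_metadata(x, metadata)
  sel <- resolve_contrast(groups, contrast)
  res <- lapply(gene_names(x), function(g) {
    a <- x$values[g, sel$a]
    b <- x$values[g, sel$b]
    gate <- suppressWarnings(normality_gate(list(a = a, b = b), config$alpha))
    tst <- two_group_test(a, b, gate)
    parametric <- tst$test_used == "T_TEST"
    data.frame(
      gene = g,
      test_used = tst$test_used,
      log2fc = log2_fold_change(a, b, parametric, config$pseudocount),
      p_value = tst$p,
      ci_low = if (parametric) tst$ci[1] else NA_real_,
      ci_high = if (parametric) tst$ci[2] else NA_real_,
      normal_a = gate[["a"]],
      normal_b = gate[["b"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_p <- bh_fdr(out$p_value, method = config$fdr_method)
  out <- out[, c("gene", "test_used", "log2fc", "p_value", "fdr_p",
                 "ci_low", "ci_high", "normal_a", "normal_b")]
  attr(out, "contrast") <- sel$label
  class(out) <- c("differential_result", "data.frame")
  out
}
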