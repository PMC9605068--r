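#' Technical normalization from positive control probes
#'
#' Removes lane-to-lane assay-efficiency differences: each lane's counts are
#' scaled by `factor_j = mean over lanes of the positive-probe summary /
#' positive-probe summary of lane j`, so that after scaling every lane has the
#' same positive-probe summary. The summary is the per-lane sum of positive
#' probe counts by default, or their geometric mean.
#'
#' @param raw a RAW-stage `count_matrix`.
#' @param panel a `panel_definition` with >= 2 positive probes.
#' @param method `"sum"` (default) or `"geomean"`.
#' @return list with `counts` (TECH_NORMALIZED `count_matrix`) and `factors`
#'   (named per-lane technical factors).
#' @export
technical_normalize <- function(raw, panel, method = c("sum", "geomean")) {
  method <- match.arg(method)
  check_stage(raw, "RAW")
  validate_panel(panel, for_normalization = TRUE)
  pos <- intersect(probes_of(panel, "POSITIVE"), gene_names(raw))
  if (length(pos) < 2) stop2("matrix carries fewer than 2 positive probes")
  summaries <- apply(raw$values[pos, , drop = FALSE], 2, function(v) {
    if (method == "sum") sum(v) else if (all(v > 0)) geomean(v) else 0
  })
  zero <- names(summaries)[summaries <= 0]
  if (length(zero) > 0) {
    stop2("lane(s) with zero positive-probe signal: ",
          paste(zero, collapse = ", "))
  }
  factors <- mean(summaries) / summaries
  vals <- sweep(raw$values, 2, factors, `*`)
  list(counts = count_matrix(vals, stage = "TECH_NORMALIZED"),
       factors = factors)
}

#' Per-lane background thresholds from negative control probes
#'
#' `threshold_j = mean + 2 * SD` of lane j's negative-control counts (sample
#' SD, n-1 denominator): the level below which a count is indistinguishable
#' from background.
#'
#' @param x a TECH_NORMALIZED `count_matrix`.
#' @param panel a `panel_definition` with >= 2 negative probes.
#' @return named numeric vector of per-lane thresholds.
#' @export
background_threshold <- function(x, panel) {
  check_stage(x, "TECH_NORMALIZED")
  neg <- intersect(probes_of(panel, "NEGATIVE"), gene_names(x))
  if (length(neg) < 2) {
    stop2("need >= 2 negative probes to estimate background (SD undefined)")
  }
  vals <- x$values[neg, , drop = FALSE]
  apply(vals, 2, function(v) mean(v) + 2 * stats::sd(v))
}

#' Subtract per-lane background thresholds
#'
#' Endogenous and housekeeping counts in lane j become
#' `max(value - threshold_j, 0)`; control probes are left untouched.
#'
#' @param x a TECH_NORMALIZED `count_matrix`.
#' @param panel a `panel_definition`.
#' @param thresholds per-lane thresholds from [background_threshold()].
#' @return a BACKGROUND_SUBTRACTED `count_matrix`.
#' @export
subtract_background <- function(x, panel, thresholds) {
  check_stage(x, "TECH_NORMALIZED")
  if (!all(sample_names(x) %in% names(thresholds))) {
    stop2("thresholds must cover every lane")
  }
  vals <- x$values
  target <- intersect(c(probes_of(panel, "ENDOGENOUS"),
                        probes_of(panel, "HOUSEKEEPING")),
                      rownames(vals))
  thr <- thresholds[colnames(vals)]
  vals[target, ] <- pmax(sweep(vals[target, , drop = FALSE], 2, thr, `-`), 0)
  count_matrix(vals, stage = "BACKGROUND_SUBTRACTED")
}

#' Biological normalization from housekeeping reference genes
#'
#' Removes input-amount differences: with `g_j` the geometric mean of the
#' usable housekeeping genes in lane j, endogenous and housekeeping counts in
#' lane j are scaled by `factor_j = mean over lanes of g_j / g_j`, equalizing
#' the housekeeping geometric mean across lanes. Housekeeping genes with a
#' zero in any lane are dropped from the geometric mean (a pseudocount would
#' break the equal-geomean identity); if none remains, that is an error
#' suggesting inspection of the background subtraction.
#'
#' @param x a BACKGROUND_SUBTRACTED `count_matrix`.
#' @param panel a `panel_definition` with >= 1 housekeeping probe.
#' @return list with `counts` (BIO_NORMALIZED `count_matrix`), `factors`
#'   (per-lane housekeeping factors) and `housekeeping_used`.
#' @export
biological_normalize <- function(x, panel) {
  check_stage(x, "BACKGROUND_SUBTRACTED")
  hk <- intersect(probes_of(panel, "HOUSEKEEPING"), gene_names(x))
  if (length(hk) < 1) stop2("matrix carries no housekeeping probe")
  hk_vals <- x$values[hk, , drop = FALSE]
  usable <- hk[apply(hk_vals > 0, 1, all)]
  if (length(usable) == 0) {
    stop2("no housekeeping gene is positive in every lane; inspect the ",
          "background subtraction (thresholds may swallow the reference genes)")
  }
  g <- apply(x$values[usable, , drop = FALSE], 2, geomean)
  factors <- mean(g) / g
  vals <- x$values
  target <- intersect(c(probes_of(panel, "ENDOGENOUS"), hk), rownames(vals))
  vals[target, ] <- sweep(vals[target, , drop = FALSE], 2, factors, `*`)
  list(counts = count_matrix(vals, stage = "BIO_NORMALIZED"),
       factors = factors, housekeeping_used = usable)
}

#' Exclude genes not expressed above background
#'
#' For each endogenous gene, a one-sided Welch two-sample t-test compares the
#' gene's counts across all samples against the pooled negative-control counts
#' across all samples (alternative: gene > negatives). A gene is retained iff
#' p < alpha; genes that cannot be distinguished from background are excluded.
#' Degenerate genes (no variance anywhere) are excluded with p recorded as 1
#' and a warning.
#'
#' @param x a `count_matrix` (applied on final values by default; see
#'   [normalize_pipeline()]).
#' @param panel a `panel_definition`.
#' @param alpha retention threshold on the one-sided p-value (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch
#'   (default FALSE).
#' @return list with `retained` (gene names), `excluded` (data frame
#'   `gene`, `p_value`) and `p_values` (named, all endogenous genes).
#' @export
background_filter <- function(x, panel, alpha = 0.05, var_equal = FALSE) {
  endo <- intersect(probes_of(panel, "ENDOGENOUS"), gene_names(x))
  neg <- intersect(probes_of(panel, "NEGATIVE"), gene_names(x))
  if (length(neg) < 2) stop2("need >= 2 negative probes")
  if (ncol(x$values) < 2) stop2("need >= 2 samples")
  negatives <- as.vector(x$values[neg, , drop = FALSE])
  p <- vapply(endo, function(g) {
    v <- x$values[g, ]
    out <- tryCatch(
      stats::t.test(v, negatives, alternative = "greater",
                    var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
    if (is.na(out)) {
      warning("gene ", g, ": degenerate background test (constant data); ",
              "excluded with p = 1", call. = FALSE)
      out <- 1
    }
    out
  }, numeric(1))
  retained <- endo[p < alpha]
  excluded <- endo[!(endo %in% retained)]
  list(retained = retained,
       excluded = data.frame(gene = excluded,
                             p_value = unname(p[excluded]),
                             stringsAsFactors = FALSE),
       p_values = p)
}

#' The full nCounter normalization chain
#'
#' Technical normalization from positive controls, negative-control
#' background thresholding and subtraction, biological normalization from
#' housekeeping genes, and exclusion of genes not expressed above background.
#' The filter runs on the final (biologically normalized) values by default;
#' `config$filter_stage = "pre"` instead evaluates it on the
#' background-subtracted matrix for sensitivity analysis (the retained set is
#' still applied to the final matrix).
#'
#' @param raw a RAW-stage `count_matrix` consistent with `panel`.
#' @param panel a `panel_definition`.
#' @param config a `run_config` (alpha, tech_factor_method, filter_stage).
#' @return list with `counts` — the BIO_NORMALIZED matrix restricted to the
#'   retained endogenous genes — and `report`, a `normalization_report` with
#'   per-lane technical factors, background thresholds, housekeeping factors,
#'   the housekeeping genes used, and the retained/excluded gene partition
#'   with p-values.
#' @export
normalize_pipeline <- function(raw, panel, config = run_config()) {
  tech <- technical_normalize(raw, panel, method = config$tech_factor_method)
  thresholds <- background_threshold(tech$counts, panel)
  sub <- subtract_background(tech$counts, panel, thresholds)
  bio <- biological_normalize(sub, panel)
  filt <- background_filter(
    if (config$filter_stage == "post") bio$counts else sub,
    panel, alpha = config$alpha)
  out <- count_matrix(
    bio$counts$values[filt$retained, , drop = FALSE],
    stage = "BIO_NORMALIZED")
  report <- structure(list(
    technical_factors = tech$factors,
    background_thresholds = thresholds,
    housekeeping_factors = bio$factors,
    housekeeping_used = bio$housekeeping_used,
    retained_genes = filt$retained,
    excluded_genes = filt$excluded,
    filter_p_values = filt$p_values,
    alpha = config$alpha,
    tech_factor_method = config$tech_factor_method,
    filter_stage = config$filter_stage
  ), class = "normalization_report")
  list(counts = out, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("<normalization_report>\n",
      "  lanes: ", length(x$technical_factors), "\n",
      "  technical factors in [",
      round(min(x$technical_factors), 3), ", ",
      round(max(x$technical_factors), 3), "]\n",
      "  background thresholds in [",
      round(min(x$background_thresholds), 2), ", ",
      round(max(x$background_thresholds), 2), "]\n",
      "  housekeeping genes used: ", length(x$housekeeping_used), "\n",
      "  retained ", length(x$retained_genes), " genes, excluded ",
      nrow(x$excluded_genes), " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
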