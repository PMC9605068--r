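#' Construct a run configuration
#'
#' One object holding every tunable of the pipeline, serializable to YAML so a
#' run can be reproduced from its config file.
#'
#' @param seed integer RNG seed for every stochastic stage.
#' @param n_permutations permutations for the GSEA null (default 1000, the
#'   depth used throughout).
#' @param alpha significance level for the background filter, the normality
#'   gate and FDR calls (default 0.05).
#' @param gsea_weight exponent on |score| in the enrichment running sum
#'   (default 1, the weighted statistic; 0 gives the unweighted
#'   Kolmogorov-Smirnov form).
#' @param permutation_mode `"GENE_SET"` (random member sets on the fixed
#'   ranking) or `"PHENOTYPE"` (shuffled group labels, re-ranked).
#' @param min_set_size,max_set_size gene-set size bounds after intersection
#'   with the measured universe (defaults 5 and 500).
#' @param projection_threshold |log2FC| at or above which a pathway member is
#'   called UP/DOWN (default 0.25).
#' @param tech_factor_method positive-probe summary behind the technical
#'   factor: `"sum"` (default) or `"geomean"`.
#' @param filter_stage apply the background expression filter after
#'   (`"post"`, default) or before (`"pre"`) biological normalization.
#' @param fdr_method multiplicity adjustment for differential tables:
#'   `"BH"` (default) or `"BY"`.
#' @param gsea_fdr gene-set FDR: `"nes_ratio"` (default, permutation-based)
#'   or `"bh"` on nominal p.
#' @param metric gene-ranking metric: `"signal2noise"` (default) or
#'   `"log2_median_ratio"`.
#' @param pseudocount added to means/medians inside log2 fold changes
#'   (default 1; guards zeros created by background subtraction).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       n_permutations = 1000L,
                       alpha = 0.05,
                       gsea_weight = 1.0,
                       permutation_mode = c("GENE_SET", "PHENOTYPE"),
                       min_set_size = 5L,
                       max_set_size = 500L,
                       projection_threshold = 0.25,
                       tech_factor_method = c("sum", "geomean"),
                       filter_stage = c("post", "pre"),
                       fdr_method = c("BH", "BY"),
                       gsea_fdr = c("nes_ratio", "bh"),
                       metric = c("signal2noise", "log2_median_ratio"),
                       pseudocount = 1.0) {
  cfg <- list(
    seed = as.integer(seed),
    n_permutations = as.integer(n_permutations),
    alpha = as.numeric(alpha),
    gsea_weight = as.numeric(gsea_weight),
    permutation_mode = match.arg(permutation_mode),
    min_set_size = as.integer(min_set_size),
    max_set_size = as.integer(max_set_size),
    projection_threshold = as.numeric(projection_threshold),
    tech_factor_method = match.arg(tech_factor_method),
    filter_stage = match.arg(filter_stage),
    fdr_method = match.arg(fdr_method),
    gsea_fdr = match.arg(gsea_fdr),
    metric = match.arg(metric),
    pseudocount = as.numeric(pseudocount)
  )
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$n_permutations < 1) stop2("n_permutations must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop2("alpha must be in (0, 1)")
  if (cfg$gsea_weight < 0) stop2("gsea_weight must be >= 0")
  if (cfg$min_set_size < 1 || cfg$max_set_size < cfg$min_set_size) {
    stop2("need 1 <= min_set_size <= max_set_size")
  }
  if (cfg$projection_threshold < 0) {
    stop2("projection_threshold must be >= 0")
  }
  if (cfg$pseudocount < 0) stop2("pseudocount must be >= 0")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg, p))`
#' reproduces `cfg` exactly.
#'
#' @param path file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
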