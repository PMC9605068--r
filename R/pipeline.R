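#' Run the full expression-to-pathway pipeline
#'
#' Normalization (technical, background, biological, expression filter), then
#' per contrast a differential table, permutation GSEA, and a pathway
#' projection for every gene set passing the GSEA FDR at `config$alpha`.
#' All outputs land in `out_dir` as TSV plus a JSON manifest; a second
#' invocation with the same inputs, config and seed reproduces the directory
#' byte for byte (wall-clock time goes to `run.log` only). On any stage error
#' the partial output directory is removed.
#'
#' @param counts a RAW-stage `count_matrix` (or path to a counts TSV).
#' @param panel a `panel_definition` (or path to a panel TSV).
#' @param metadata a `sample_metadata` (or path to a metadata TSV).
#' @param collection a `gene_set_collection` (or path to a GMT file).
#' @param config a `run_config`.
#' @param out_dir results directory, created if needed.
#' @param contrasts character vector of group labels, each analysed
#'   one-vs-rest; default all groups with >= 2 groups present.
#' @return invisibly, the manifest list (also written as `manifest.json`):
#'   config snapshot, package version, input digests, per-stage row counts,
#'   output digests.
#' @export
run_pipeline <- function(counts, panel, metadata, collection,
                         config = run_config(), out_dir,
                         contrasts = NULL) {
  input_digests <- list()
  if (is.character(counts)) {
    input_digests$counts <- unname(tools::md5sum(counts))
  }
  if (is.character(panel)) {
    input_digests$panel <- unname(tools::md5sum(panel))
    panel <- read_panel(panel)
  }
  if (is.character(counts)) counts <- read_count_matrix(counts, panel)
  if (is.character(metadata)) {
    input_digests$metadata <- unname(tools::md5sum(metadata))
    metadata <- read_metadata(metadata)
  }
  if (is.character(collection)) {
    input_digests$gene_sets <- unname(tools::md5sum(collection))
    collection <- read_gmt(collection)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)  # truncate
  stage <- "setup"
  manifest <- tryCatch({
    log_line("pipeline start, seed ", config$seed)

    stage <- "normalization"
    norm <- normalize_pipeline(counts, panel, config)
    write_count_matrix(norm$counts, file.path(out_dir, "normalized_counts.tsv"))
    jsonlite::write_json(
      normalization_report_json(norm$report),
      file.path(out_dir, "normalization_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("normalization: retained ", length(norm$report$retained_genes),
             " of ", length(norm$report$filter_p_values), " endogenous genes")

    stage <- "gene-set filtering"
    filtered <- filter_gene_sets(collection, gene_names(norm$counts),
                                 min_size = config$min_set_size,
                                 max_size = config$max_set_size,
                                 verbose = FALSE)
    log_line("gene sets: ", length(filtered), " of ", length(collection),
             " usable")

    groups <- check_metadata(norm$counts, metadata)
    if (is.null(contrasts)) contrasts <- unique(groups)
    counts_per_stage <- list(
      raw_genes = nrow(counts$values),
      retained_genes = nrow(norm$counts$values),
      gene_sets_used = length(filtered))
    outputs <- c("normalized_counts.tsv", "normalization_report.json")

    for (g in contrasts) {
      stage <- paste0("differential expression (", g, ")")
      diff <- differential_table(norm$counts, metadata, g, config)
      diff_path <- file.path(out_dir,
                             paste0("differential_", safe_name(g), ".tsv"))
      write_tsv_file(format_numeric_df(diff), diff_path)
      outputs <- c(outputs, basename(diff_path))
      log_line(attr(diff, "contrast"), ": ",
               sum(diff$fdr_p <= config$alpha), " genes at FDR <= ",
               config$alpha)

      stage <- paste0("gene-set enrichment (", g, ")")
      gsea <- score_gene_sets(norm$counts, metadata, g, filtered, config)
      gsea_path <- file.path(out_dir, paste0("gsea_", safe_name(g), ".tsv"))
      write_tsv_file(format_numeric_df(gsea), gsea_path)
      outputs <- c(outputs, basename(gsea_path))
      enriched <- gsea$set[!is.na(gsea$fdr_q) & gsea$fdr_q <= config$alpha]
      log_line(attr(gsea, "contrast"), ": ", length(enriched),
               " sets at fdr_q <= ", config$alpha)

      stage <- paste0("pathway projection (", g, ")")
      for (s in enriched) {
        proj <- project_pathway(diff, filtered$sets[[s]],
                                threshold = config$projection_threshold,
                                pathway = s)
        proj_path <- file.path(
          out_dir, paste0("projection_", safe_name(g), "_",
                          safe_name(s), ".tsv"))
        write_tsv_file(format_numeric_df(proj$table), proj_path)
        outputs <- c(outputs, basename(proj_path))
      }
    }

    stage <- "manifest"
    manifest <- list(
      package = "countpath",
      version = as.character(utils::packageVersion("countpath")),
      seed = config$seed,
      config = unclass(config),
      contrasts = as.list(contrasts),
      input_digests = input_digests,
      stage_counts = counts_per_stage,
      output_digests = as.list(
        setNames(unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("pipeline done")
    manifest
  }, error = function(e) {
    unlink(out_dir, recursive = TRUE)
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(manifest)
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# round-trip-stable numeric formatting for TSV output
format_numeric_df <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE)
      }, character(1))
    }
  }
  df
}

normalization_report_json <- function(report) {
  list(
    technical_factors = as.list(report$technical_factors),
    background_thresholds = as.list(report$background_thresholds),
    housekeeping_factors = as.list(report$housekeeping_factors),
    housekeeping_used = report$housekeeping_used,
    alpha = report$alpha,
    tech_factor_method = report$tech_factor_method,
    filter_stage = report$filter_stage,
    retained_genes = report$retained_genes,
    excluded_genes = report$excluded_genes
  )
}

#' Render a human-readable report from a completed run directory
#'
#' Purely derived from the TSV/JSON outputs of [run_pipeline()]; nothing is
#' recomputed. Missing stage outputs are noted as gaps rather than failing.
#' Regeneration is idempotent.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @param alpha FDR threshold used to list enriched pathways (default from
#'   the manifest).
#' @return invisibly, the path of the written `report.md`.
#' @export
render_report <- function(results_dir, alpha = NULL) {
  lines <- c("# Expression-to-pathway run report", "")
  manifest_path <- file.path(results_dir, "manifest.json")
  manifest <- NULL
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    if (is.null(alpha)) alpha <- manifest$config$alpha
    lines <- c(lines,
               paste0("Seed ", manifest$seed, "; ",
                      manifest$stage_counts$retained_genes, " of ",
                      manifest$stage_counts$raw_genes,
                      " panel probes retained after normalization and ",
                      "background filtering; ",
                      manifest$stage_counts$gene_sets_used,
                      " gene sets analysed."),
               "")
  } else {
    lines <- c(lines, "_Gap: manifest.json missing._", "")
  }
  if (is.null(alpha)) alpha <- 0.05
  norm_path <- file.path(results_dir, "normalization_report.json")
  if (file.exists(norm_path)) {
    nr <- jsonlite::read_json(norm_path)
    tf <- unlist(nr$technical_factors)
    bt <- unlist(nr$background_thresholds)
    lines <- c(lines, "## Normalization", "",
               paste0("Technical factors span [",
                      signif(min(tf), 4), ", ", signif(max(tf), 4),
                      "]; background thresholds (mean + 2SD of negatives) ",
                      "span [", signif(min(bt), 4), ", ", signif(max(bt), 4),
                      "]."),
               paste0(length(nr$excluded_genes$gene %||% nr$excluded_genes),
                      " genes excluded as not expressed above background."),
               "")
  } else {
    lines <- c(lines, "_Gap: normalization_report.json missing._", "")
  }
  contrasts <- if (!is.null(manifest)) unlist(manifest$contrasts) else
    sub("^gsea_(.*)\\.tsv$", "\\1",
        list.files(results_dir, pattern = "^gsea_.*\\.tsv$"))
  for (g in contrasts) {
    lines <- c(lines, paste0("## Contrast: ", g, " vs rest"), "")
    gsea_path <- file.path(results_dir, paste0("gsea_", safe_name(g), ".tsv"))
    if (file.exists(gsea_path)) {
      gs <- read_tsv_file(gsea_path)
      top <- gs[!is.na(gs$fdr_q) & gs$fdr_q <= alpha, , drop = FALSE]
      if (nrow(top) == 0) {
        lines <- c(lines,
                   paste0("No gene set at fdr_q <= ", alpha, "."), "")
      } else {
        lines <- c(lines, paste0("Enriched gene sets (fdr_q <= ", alpha, "):"),
                   "",
                   "| set | size | ES | NES | p | q |",
                   "|---|---|---|---|---|---|",
                   vapply(seq_len(nrow(top)), function(i) {
                     sprintf("| %s | %d | %.3f | %.3f | %.4g | %.4g |",
                             top$set[i], as.integer(top$size_used[i]),
                             as.numeric(top$es[i]), as.numeric(top$nes[i]),
                             as.numeric(top$p_nominal[i]),
                             as.numeric(top$fdr_q[i]))
                   }, character(1)),
                   "")
      }
    } else {
      lines <- c(lines, "_Gap: GSEA table missing._", "")
    }
    projs <- list.files(results_dir,
                        pattern = paste0("^projection_", safe_name(g), "_.*\\.tsv$"))
    for (p in projs) {
      pt <- read_tsv_file(file.path(results_dir, p))
      nm <- sub(paste0("^projection_", safe_name(g), "_(.*)\\.tsv$"), "\\1", p)
      lines <- c(lines, sprintf(
        "Projection %s: %d up, %d down, %d indifferent.",
        nm, sum(pt$state == "UP"), sum(pt$state == "DOWN"),
        sum(pt$state == "INDIFFERENT")))
    }
    if (length(projs) > 0) lines <- c(lines, "")
  }
  out <- file.path(results_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
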