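#' Processing stages of a count matrix
#'
#' Counts move through the chain RAW -> TECH_NORMALIZED ->
#' BACKGROUND_SUBTRACTED -> BIO_NORMALIZED; each normalization step checks the
#' stage of its input so steps cannot be applied out of order or twice.
#'
#' @export
COUNT_STAGES <- c("RAW", "TECH_NORMALIZED", "BACKGROUND_SUBTRACTED",
                  "BIO_NORMALIZED")

#' Construct a count matrix
#'
#' A gene-by-sample grid of non-negative values with a processing stage.
#' Samples are nCounter lanes. RAW-stage values must be integers.
#'
#' @param values numeric matrix, genes as rows, samples as columns, with
#'   dimnames set.
#' @param stage one of [COUNT_STAGES].
#' @param panel optional `panel_definition`; when given, every gene must be a
#'   probe of the panel.
#' @return a `count_matrix`: list with elements `values` (matrix) and `stage`.
#' @export
count_matrix <- function(values, stage = "RAW", panel = NULL) {
  stage <- match.arg(stage, COUNT_STAGES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("count matrix needs gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) {
    stop2("duplicate gene name(s): ",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop2("duplicate sample name(s): ",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  }
  if (!all(is.finite(values))) stop2("count matrix values must be finite")
  if (any(values < 0)) stop2("count matrix values must be >= 0")
  if (stage == "RAW" && any(values != round(values))) {
    stop2("RAW-stage counts must be integers")
  }
  if (!is.null(panel)) {
    unknown <- setdiff(rownames(values), panel$probe_name)
    if (length(unknown) > 0) {
      stop2("gene(s) not in panel: ",
            paste(utils::head(unknown, 10), collapse = ", "))
    }
  }
  structure(list(values = values, stage = stage), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, stage ", x$stage, "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Gene and sample names of a count matrix
#' @param x a `count_matrix`.
#' @return character vector.
#' @export
gene_names <- function(x) rownames(x$values)

#' @rdname gene_names
#' @export
sample_names <- function(x) colnames(x$values)

# stage guard used by the normalization steps
check_stage <- function(x, expected) {
  if (!inherits(x, "count_matrix")) stop2("expected a count_matrix")
  if (x$stage != expected) {
    stop2("count matrix is at stage ", x$stage, "; this step needs ", expected)
  }
  invisible(x)
}

#' Read a count matrix TSV
#'
#' The file has a header row of sample names, gene names in the first column,
#' and integer cells. Malformed input is rejected with the offending
#' coordinates rather than coerced.
#'
#' @param path file path.
#' @param panel optional `panel_definition` to check gene names against;
#'   genes absent from the panel cause rejection.
#' @return a RAW-stage `count_matrix` preserving the file's row and column
#'   order.
#' @export
read_count_matrix <- function(path, panel = NULL) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop2(path, ": need a gene column plus >= 1 sample")
  genes <- raw[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop2(path, ": duplicate gene row(s): ",
          paste(unique(dup), collapse = ", "))
  }
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    cell <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad) > 0) {
      i <- bad[1]
      stop2(path, ": invalid count '", cell[i], "' at row ", i,
            " (gene ", genes[i], "), column ", j, " (sample ", samples[j], ")")
    }
    vals[, j] <- num
  }
  count_matrix(vals, stage = "RAW", panel = panel)
}

#' Write a count matrix TSV
#'
#' Inverse of [read_count_matrix()] for RAW matrices; normalized matrices are
#' written with full numeric precision.
#'
#' @param x a `count_matrix`.
#' @param path file path.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
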