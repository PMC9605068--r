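#' Construct sample metadata
#'
#' Maps each sample (lane) to exactly one group label — the response variable
#' of every between-group contrast.
#'
#' @param sample character vector of sample names.
#' @param group character vector of group labels, same length.
#' @return a `sample_metadata` data frame with columns `sample`, `group`.
#' @export
sample_metadata <- function(sample, group) {
  sample <- as.character(sample)
  group <- as.character(group)
  if (length(sample) != length(group)) {
    stop2("sample and group must have equal length")
  }
  if (anyDuplicated(sample)) {
    stop2("duplicate sample name(s): ",
          paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  if (any(is.na(group) | group == "")) stop2("empty group label")
  structure(data.frame(sample = sample, group = group,
                       stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}

#' Check that metadata covers a count matrix
#'
#' Every sample of the matrix must carry exactly one group label; any
#' between-group statistic additionally needs >= 2 samples per group.
#'
#' @param x a `count_matrix`.
#' @param metadata a `sample_metadata`.
#' @param min_per_group minimum group size to enforce (default 2).
#' @return invisibly, the group label vector aligned to the matrix columns.
#' @export
check_metadata <- function(x, metadata, min_per_group = 2) {
  missing <- setdiff(sample_names(x), metadata$sample)
  if (length(missing) > 0) {
    stop2("sample(s) without group label: ", paste(missing, collapse = ", "))
  }
  groups <- metadata$group[match(sample_names(x), metadata$sample)]
  n <- table(groups)
  if (any(n < min_per_group)) {
    stop2("group(s) with fewer than ", min_per_group, " samples: ",
          paste(names(n)[n < min_per_group], collapse = ", "))
  }
  invisible(groups)
}

#' Read / write sample metadata TSV
#'
#' Columns `sample`, `group`.
#'
#' @param path file path.
#' @return `read_metadata` returns a `sample_metadata`.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("sample", "group") %in% names(df))) {
    stop2(path, ": metadata TSV needs columns sample, group")
  }
  sample_metadata(df$sample, df$group)
}

#' @rdname read_metadata
#' @param metadata a `sample_metadata`.
#' @export
write_metadata <- function(metadata, path) {
  write_tsv_file(as.data.frame(metadata), path)
}
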