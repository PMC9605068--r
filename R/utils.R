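# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Geometric mean
#'
#' @param x numeric vector of strictly positive values.
#' @return the geometric mean of `x`.
#' @keywords internal
geomean <- function(x) {
  if (any(x <= 0)) stop2("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# write.table with the settings used for every TSV the package emits, so that
# outputs are byte-stable across runs.
write_tsv_file <- function(df, path, row.names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = row.names, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}
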