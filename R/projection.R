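#' Project differential results onto a pathway
#'
#' The tabular analogue of a colored pathway diagram: each measured member of
#' the pathway is classified from its log2 fold change as `UP`
#' (log2FC >= +threshold), `DOWN` (<= -threshold) or `INDIFFERENT` (the rest;
#' genes with an undefined fold change fall here and are flagged).
#'
#' @param diff a `differential_result` table ([differential_table()]).
#' @param members character vector: the pathway's gene members.
#' @param threshold non-negative |log2FC| cutoff (default 0.25).
#' @param pathway name used in the output (default "pathway").
#' @return a `pathway_projection`: list with `pathway`, `contrast`,
#'   `threshold`, `table` (`gene`, `log2fc`, `state`) and `counts`
#'   (`n_up`, `n_down`, `n_indifferent`).
#' @export
project_pathway <- function(diff, members, threshold = 0.25,
                            pathway = "pathway") {
  if (threshold < 0) stop2("threshold must be >= 0")
  rows <- diff[diff$gene %in% members, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop2("pathway '", pathway, "' has no measured member in the table")
  }
  lfc <- rows$log2fc
  state <- ifelse(!is.finite(lfc), "INDIFFERENT",
                  ifelse(lfc >= threshold, "UP",
                         ifelse(lfc <= -threshold, "DOWN", "INDIFFERENT")))
  if (any(!is.finite(lfc))) {
    warning("pathway '", pathway, "': ", sum(!is.finite(lfc)),
            " gene(s) with undefined log2FC marked INDIFFERENT",
            call. = FALSE)
  }
  tab <- data.frame(gene = rows$gene, log2fc = lfc, state = state,
                    stringsAsFactors = FALSE)
  structure(list(
    pathway = pathway,
    contrast = attr(diff, "contrast"),
    threshold = threshold,
    table = tab,
    counts = c(n_up = sum(state == "UP"),
               n_down = sum(state == "DOWN"),
               n_indifferent = sum(state == "INDIFFERENT"))
  ), class = "pathway_projection")
}

#' @export
print.pathway_projection <- function(x, ...) {
  cat("<pathway_projection> ", x$pathway, " (", x$contrast, "), |log2FC| >= ",
      x$threshold, ": ", x$counts[["n_up"]], " up, ", x$counts[["n_down"]],
      " down, ", x$counts[["n_indifferent"]], " indifferent\n", sep = "")
  invisible(x)
}
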