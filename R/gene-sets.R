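#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members per set). Members must
#'   be non-empty and unique within a set.
#' @param descriptions optional named character vector of per-set descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop2("every gene set needs a name")
  }
  if (anyDuplicated(names(sets))) {
    stop2("duplicate set name(s): ",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) stop2("gene set '", nm, "' is empty")
    if (anyDuplicated(sets[[nm]])) {
      stop2("gene set '", nm, "' has duplicate members")
    }
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  descriptions <- descriptions[names(sets)]
  descriptions[is.na(descriptions)] <- ""
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("<gene_set_collection> ", length(x$sets), " sets, sizes ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then members. Empty lines are skipped; duplicate members within a line are
#' deduplicated with a warning; a line with fewer than 3 fields or a repeated
#' set name is an error naming the line.
#'
#' @param path file path.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop2(path, ": line ", i, " has fewer than 3 tab-separated fields")
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop2(path, ": line ", i, ": duplicate set name '", name, "'")
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("set '", name, "' (line ", i, "): duplicate members collapsed",
              call. = FALSE)
      members <- unique(members)
    }
    sets[[name]] <- members
    descriptions[name] <- fields[2]
  }
  gene_set_collection(sets, descriptions)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path file path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$descriptions[[nm]]
    if (!nzchar(desc)) desc <- "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to a measured universe and size bounds
#'
#' Each set is intersected with the measured gene universe; sets whose
#' intersection falls outside `[min_size, max_size]` are dropped (the GSEA
#' size-filtering convention). Drop decisions are reported via `message()`.
#'
#' @param collection a `gene_set_collection`.
#' @param universe character vector of measured gene names.
#' @param min_size,max_size inclusive size bounds on the intersected sets.
#' @param verbose emit a message per dropped set (default TRUE).
#' @return the filtered `gene_set_collection`.
#' @export
filter_gene_sets <- function(collection, universe, min_size = 5,
                             max_size = 500, verbose = TRUE) {
  if (length(universe) == 0) stop2("empty gene universe")
  kept <- list()
  for (nm in names(collection$sets)) {
    inter <- intersect(collection$sets[[nm]], universe)
    if (length(inter) < min_size || length(inter) > max_size) {
      if (verbose) {
        message("dropping set '", nm, "': ", length(inter),
                " measured members outside [", min_size, ", ", max_size, "]")
      }
      next
    }
    kept[[nm]] <- inter
  }
  if (length(kept) == 0) {
    stop2("no gene set survives size filtering; relax min_size/max_size ",
          "or check that set members match the measured gene names")
  }
  gene_set_collection(kept, collection$descriptions[names(kept)])
}
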