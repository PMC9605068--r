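#' Read NanoString RCC lane files
#'
#' Each RCC file is one lane: bracketed sections (`<Header>` ... `</Header>`)
#' holding comma-separated key/value rows, with the counts in a
#' `Code_Summary` section whose rows are `CodeClass,Name,Accession,Count`.
#' CodeClass values map Endogenous -> ENDOGENOUS, Housekeeping ->
#' HOUSEKEEPING, Positive -> POSITIVE, Negative -> NEGATIVE; the conventional
#' positive-probe name suffix `POS_X(cc)` supplies the spike concentration.
#' Unknown sections are ignored with a warning.
#'
#' @param paths character vector of RCC file paths, one per lane.
#' @param panel optional `panel_definition`; when given, the probe catalogue
#'   inferred from the files must match it. All lanes must agree on the probe
#'   catalogue regardless.
#' @return list with elements `counts` (a RAW-stage `count_matrix`, one column
#'   per file) and `panel` (the inferred `panel_definition`).
#' @export
read_rcc <- function(paths, panel = NULL) {
  if (length(paths) == 0) stop2("no RCC files given")
  lanes <- lapply(paths, parse_rcc_file)
  probes <- lanes[[1]]$code_summary$Name
  for (k in seq_along(lanes)[-1]) {
    other <- lanes[[k]]$code_summary$Name
    if (!identical(sort(probes), sort(other))) {
      diff <- union(setdiff(probes, other), setdiff(other, probes))
      stop2("probe lists differ between lanes '", basename(paths[1]),
            "' and '", basename(paths[k]), "': ",
            paste(diff, collapse = ", "))
    }
  }
  inferred <- rcc_panel(lanes[[1]]$code_summary)
  if (!is.null(panel)) {
    if (!isTRUE(all.equal(as.data.frame(panel)[order(panel$probe_name), ],
                          as.data.frame(inferred)[order(inferred$probe_name), ],
                          check.attributes = FALSE))) {
      stop2("panel inferred from RCC files does not match the supplied panel")
    }
  }
  sample_ids <- vapply(seq_along(lanes), function(k) {
    id <- lanes[[k]]$sample_id
    if (is.null(id) || !nzchar(id)) {
      id <- sub("\\.[Rr][Cc][Cc]$", "", basename(paths[k]))
    }
    id
  }, character(1))
  vals <- matrix(NA_real_, nrow = length(probes), ncol = length(lanes),
                 dimnames = list(probes, sample_ids))
  for (k in seq_along(lanes)) {
    cs <- lanes[[k]]$code_summary
    vals[cs$Name, k] <- cs$Count
  }
  list(counts = count_matrix(vals, stage = "RAW", panel = inferred),
       panel = inferred)
}

# Parse one RCC file into its sections.
parse_rcc_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  open <- grep("^<[^/].*>$", lines)
  sections <- list()
  known <- c("Header", "Sample_Attributes", "Lane_Attributes",
             "Code_Summary", "Messages")
  for (i in open) {
    name <- sub("^<(.*)>$", "\\1", lines[i])
    close <- grep(paste0("^</", name, ">$"), lines)
    close <- close[close > i]
    if (length(close) == 0) {
      stop2(path, ": section <", name, "> is never closed")
    }
    if (!name %in% known) {
      warning(path, ": ignoring unknown RCC section <", name, ">",
              call. = FALSE)
      next
    }
    sections[[name]] <- lines[(i + 1):(close[1] - 1)]
  }
  if (is.null(sections$Code_Summary)) {
    stop2(path, ": missing Code_Summary section")
  }
  cs <- read.csv(text = paste(sections$Code_Summary, collapse = "\n"),
                 header = TRUE, stringsAsFactors = FALSE)
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% names(cs))) {
    stop2(path, ": Code_Summary needs columns CodeClass, Name, Accession, Count")
  }
  cs$Count <- suppressWarnings(as.numeric(cs$Count))
  if (any(is.na(cs$Count) | cs$Count < 0)) {
    stop2(path, ": non-numeric or negative Count in Code_Summary")
  }
  sample_id <- NULL
  if (!is.null(sections$Sample_Attributes)) {
    kv <- strsplit(sections$Sample_Attributes, ",", fixed = TRUE)
    for (f in kv) if (length(f) >= 2 && f[1] == "ID") sample_id <- f[2]
  }
  list(code_summary = cs, sample_id = sample_id)
}

# Build a panel_definition from a Code_Summary data frame.
rcc_panel <- function(cs) {
  map <- c(Endogenous = "ENDOGENOUS", Housekeeping = "HOUSEKEEPING",
           Positive = "POSITIVE", Negative = "NEGATIVE")
  base_class <- sub("[0-9]+$", "", cs$CodeClass)  # e.g. Endogenous1
  unknown <- setdiff(unique(base_class), names(map))
  if (length(unknown) > 0) {
    stop2("unknown CodeClass value(s): ", paste(unknown, collapse = ", "))
  }
  cls <- unname(map[base_class])
  conc <- rep(NA_real_, nrow(cs))
  pos <- cls == "POSITIVE"
  m <- regmatches(cs$Name[pos],
                  regexec("\\(([0-9.]+)\\)\\s*$", cs$Name[pos]))
  parsed <- vapply(m, function(g) {
    if (length(g) == 2) as.numeric(g[2]) else NA_real_
  }, numeric(1))
  conc[pos] <- parsed
  if (any(pos & is.na(conc))) {
    # no parsable concentration: fall back to a nominal 4-fold ladder so the
    # panel still validates (technical normalization only needs the counts)
    k <- sum(pos & is.na(conc))
    conc[pos & is.na(conc)] <- 128 / 4^(seq_len(k) - 1)
  }
  panel_definition(cs$Name, cls, conc)
}
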