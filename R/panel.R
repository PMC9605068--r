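#' Probe classes recognised in an nCounter-style code set
#'
#' Endogenous probes measure the transcripts of interest; housekeeping
#' (reference) probes drive biological normalization; positive control probes
#' are spiked at known concentrations (fM) and drive technical normalization;
#' negative control probes have no target and measure background.
#'
#' @export
PROBE_CLASSES <- c("ENDOGENOUS", "HOUSEKEEPING", "POSITIVE", "NEGATIVE")

#' Construct a panel definition
#'
#' A panel definition is the code-set contract every other object is checked
#' against: an ordered probe catalogue with a class per probe and a spike-in
#' concentration (fM) for positive control probes.
#'
#' @param probe_name character vector of unique probe names.
#' @param probe_class character vector, one of [PROBE_CLASSES] per probe.
#' @param concentration numeric vector of spike-in concentrations; must be a
#'   positive number exactly for `POSITIVE` probes and `NA` otherwise.
#' @return a `panel_definition`: a data frame with columns `probe_name`,
#'   `probe_class`, `concentration`.
#' @export
panel_definition <- function(probe_name, probe_class, concentration = NULL) {
  probe_name <- as.character(probe_name)
  probe_class <- as.character(probe_class)
  if (is.null(concentration)) concentration <- rep(NA_real_, length(probe_name))
  if (length(probe_class) != length(probe_name) ||
      length(concentration) != length(probe_name)) {
    stop2("probe_name, probe_class and concentration must have equal length")
  }
  panel <- data.frame(probe_name = probe_name,
                      probe_class = probe_class,
                      concentration = as.numeric(concentration),
                      stringsAsFactors = FALSE)
  class(panel) <- c("panel_definition", "data.frame")
  validate_panel(panel)
  panel
}

#' Validate a panel definition
#'
#' @param panel a `panel_definition`.
#' @param for_normalization if `TRUE`, additionally require the control-probe
#'   minimums normalization needs: at least 1 housekeeping, 2 negative and 2
#'   positive probes.
#' @return the panel, invisibly.
#' @export
validate_panel <- function(panel, for_normalization = FALSE) {
  if (!all(c("probe_name", "probe_class", "concentration") %in% names(panel))) {
    stop2("panel must have columns probe_name, probe_class, concentration")
  }
  bad <- setdiff(unique(panel$probe_class), PROBE_CLASSES)
  if (length(bad) > 0) {
    stop2("unknown probe class(es): ", paste(bad, collapse = ", "))
  }
  dup <- panel$probe_name[duplicated(panel$probe_name)]
  if (length(dup) > 0) {
    stop2("duplicate probe name(s): ", paste(unique(dup), collapse = ", "))
  }
  pos <- panel$probe_class == "POSITIVE"
  if (any(pos & (is.na(panel$concentration) | panel$concentration <= 0))) {
    stop2("every POSITIVE probe needs a positive concentration")
  }
  if (any(!pos & !is.na(panel$concentration))) {
    stop2("concentration is only allowed on POSITIVE probes")
  }
  if (for_normalization) {
    n <- table(factor(panel$probe_class, levels = PROBE_CLASSES))
    if (n[["HOUSEKEEPING"]] < 1 || n[["NEGATIVE"]] < 2 || n[["POSITIVE"]] < 2) {
      stop2("normalization needs >= 1 HOUSEKEEPING, >= 2 NEGATIVE and ",
            ">= 2 POSITIVE probes; panel has ",
            n[["HOUSEKEEPING"]], "/", n[["NEGATIVE"]], "/", n[["POSITIVE"]])
    }
  }
  invisible(panel)
}

#' Names of the probes of one class
#'
#' @param panel a `panel_definition`.
#' @param class one of [PROBE_CLASSES].
#' @return character vector of probe names.
#' @export
probes_of <- function(panel, class) {
  class <- match.arg(class, PROBE_CLASSES)
  panel$probe_name[panel$probe_class == class]
}

#' Read / write a panel definition TSV
#'
#' Columns: `probe_name`, `probe_class`, `concentration` (empty for
#' non-positive probes).
#'
#' @param path file path.
#' @return `read_panel` returns a `panel_definition`.
#' @export
read_panel <- function(path) {
  df <- read_tsv_file(path)
  need <- c("probe_name", "probe_class")
  if (!all(need %in% names(df))) {
    stop2(path, ": panel TSV needs columns probe_name, probe_class")
  }
  conc <- if ("concentration" %in% names(df)) {
    suppressWarnings(as.numeric(df$concentration))
  } else {
    rep(NA_real_, nrow(df))
  }
  panel_definition(df$probe_name, df$probe_class, conc)
}

#' @rdname read_panel
#' @param panel a `panel_definition`.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  write_tsv_file(as.data.frame(panel), path)
}
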