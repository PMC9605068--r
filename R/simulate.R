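#' Specify a synthetic nCounter panel simulation
#'
#' Defines a multiplexed code set (endogenous, housekeeping, positive and
#' negative probes), a group design, and the generative model for counts:
#' endogenous gene i in group g and lane j is drawn as
#' `NegBinomial(mean = t_j * 2^(b_i + delta_ig), dispersion) +
#' Poisson(background_mean)`, with lane technical factor
#' `t_j ~ LogNormal(0, lane_factor_sd)`; housekeeping genes have `delta = 0`;
#' positive probes have mean `t_j * concentration * pos_scale` plus
#' background; negative probes are pure background (`Poisson(background_mean)`,
#' independent of the lane factor). `delta_ig` equals `log2fc` for the first
#' `ceiling(affected_fraction * m)` members of each spiked set in its target
#' group and 0 elsewhere.
#'
#' @param n_endogenous,n_housekeeping,n_positive,n_negative probe counts per
#'   class; normalization needs `n_negative >= 2`, `n_positive >= 2`,
#'   `n_housekeeping >= 1`.
#' @param groups named integer vector: samples per group (each >= 2).
#' @param baseline_log2_mean_range length-2 numeric: per-gene baseline log2
#'   means are drawn uniformly from this range.
#' @param baseline_log2_means optional explicit per-gene baselines
#'   (length `n_endogenous + n_housekeeping`, endogenous first) overriding the
#'   range; `-Inf` gives a gene with no signal above background.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param lane_factor_sd lognormal sigma of the per-lane technical factor.
#' @param background_mean Poisson mean of additive background at
#'   negative-control level, common to all probe classes.
#' @param pos_scale counts per fM per unit lane factor for positive probes.
#' @param spiked_sets list of spikes, each a list with fields `name`,
#'   `members` (endogenous gene names), `log2fc`, `affected_fraction` in
#'   (0, 1], `target_group`.
#' @param extra_sets optional named list of additional (unspiked) gene sets
#'   included in the design's collection.
#' @param seed integer RNG seed; the simulation is fully reproducible from it.
#' @return a `simulation_design`.
#' @export
simulation_design <- function(n_endogenous = 300L,
                              n_housekeeping = 30L,
                              n_positive = 6L,
                              n_negative = 8L,
                              groups = c(A = 6L, B = 6L),
                              baseline_log2_mean_range = c(5, 10),
                              baseline_log2_means = NULL,
                              nb_dispersion = 0.1,
                              lane_factor_sd = 0.2,
                              background_mean = 5,
                              pos_scale = 30,
                              spiked_sets = list(),
                              extra_sets = list(),
                              seed = 1L) {
  design <- structure(list(
    n_endogenous = as.integer(n_endogenous),
    n_housekeeping = as.integer(n_housekeeping),
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    groups = groups,
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    baseline_log2_means = baseline_log2_means,
    nb_dispersion = as.numeric(nb_dispersion),
    lane_factor_sd = as.numeric(lane_factor_sd),
    background_mean = as.numeric(background_mean),
    pos_scale = as.numeric(pos_scale),
    spiked_sets = spiked_sets,
    extra_sets = extra_sets,
    seed = as.integer(seed)
  ), class = "simulation_design")
  validate_design(design)
  design
}

validate_design <- function(d) {
  if (d$n_negative < 2 || d$n_positive < 2 || d$n_housekeeping < 1) {
    stop2("design needs >= 2 negative, >= 2 positive, >= 1 housekeeping probe")
  }
  if (d$n_endogenous < 1) stop2("need at least one endogenous gene")
  if (is.null(names(d$groups)) || any(names(d$groups) == "")) {
    stop2("groups must be a named vector of sample sizes")
  }
  if (any(d$groups < 2)) stop2("every group needs >= 2 samples")
  if (length(d$baseline_log2_mean_range) != 2 ||
      diff(d$baseline_log2_mean_range) < 0) {
    stop2("baseline_log2_mean_range must be (low, high)")
  }
  if (!is.null(d$baseline_log2_means) &&
      length(d$baseline_log2_means) != d$n_endogenous + d$n_housekeeping) {
    stop2("baseline_log2_means must cover endogenous + housekeeping genes")
  }
  if (d$nb_dispersion < 0) stop2("nb_dispersion must be >= 0")
  if (d$lane_factor_sd < 0) stop2("lane_factor_sd must be >= 0")
  if (d$background_mean < 0) stop2("background_mean must be >= 0")
  gene_pool <- sprintf("GENE_%04d", seq_len(d$n_endogenous))
  for (s in d$spiked_sets) {
    need <- c("name", "members", "log2fc", "affected_fraction", "target_group")
    if (!all(need %in% names(s))) {
      stop2("each spiked set needs fields: ", paste(need, collapse = ", "))
    }
    if (!all(s$members %in% gene_pool)) {
      stop2("spiked set '", s$name, "' has members outside the endogenous genes")
    }
    if (s$affected_fraction <= 0 || s$affected_fraction > 1) {
      stop2("affected_fraction must be in (0, 1]")
    }
    if (!s$target_group %in% names(d$groups)) {
      stop2("spiked set '", s$name, "' targets unknown group '",
            s$target_group, "'")
    }
  }
  invisible(d)
}

#' Build the panel implied by a simulation design
#'
#' Deterministic (no randomness): endogenous genes `GENE_0001...`,
#' housekeeping `HK_01...`, positive controls `POS_A(128)`, `POS_B(32)`, ...
#' on a 4-fold concentration ladder starting at 128 fM, negatives `NEG_01...`.
#'
#' @param design a `simulation_design`.
#' @return a `panel_definition` with exactly the designed class counts.
#' @export
simulate_panel <- function(design) {
  validate_design(design)
  conc <- 128 / 4^(seq_len(design$n_positive) - 1)
  pos_names <- sprintf("POS_%s(%s)", LETTERS[seq_len(design$n_positive)],
                       format(conc, trim = TRUE, drop0trailing = TRUE,
                              scientific = FALSE))
  panel_definition(
    probe_name = c(sprintf("GENE_%04d", seq_len(design$n_endogenous)),
                   sprintf("HK_%02d", seq_len(design$n_housekeeping)),
                   pos_names,
                   sprintf("NEG_%02d", seq_len(design$n_negative))),
    probe_class = rep(c("ENDOGENOUS", "HOUSEKEEPING", "POSITIVE", "NEGATIVE"),
                      times = c(design$n_endogenous, design$n_housekeeping,
                                design$n_positive, design$n_negative)),
    concentration = c(rep(NA_real_,
                          design$n_endogenous + design$n_housekeeping),
                      conc,
                      rep(NA_real_, design$n_negative))
  )
}

# per-gene, per-group log2 effect matrix from the spiked sets
design_effects <- function(design) {
  genes <- sprintf("GENE_%04d", seq_len(design$n_endogenous))
  delta <- matrix(0, nrow = design$n_endogenous, ncol = length(design$groups),
                  dimnames = list(genes, names(design$groups)))
  affected <- list()
  for (s in design$spiked_sets) {
    k <- ceiling(s$affected_fraction * length(s$members))
    hit <- s$members[seq_len(k)]
    delta[hit, s$target_group] <- delta[hit, s$target_group] + s$log2fc
    affected[[s$name]] <- hit
  }
  list(delta = delta, affected = affected)
}

#' The gene-set collection carried by a simulation design
#'
#' Spiked sets first, then any extra (unspiked) sets.
#'
#' @param design a `simulation_design`.
#' @return a `gene_set_collection`.
#' @export
design_collection <- function(design) {
  sets <- c(setNames(lapply(design$spiked_sets, `[[`, "members"),
                     vapply(design$spiked_sets, `[[`, character(1), "name")),
            design$extra_sets)
  if (length(sets) == 0) stop2("design carries no gene sets")
  gene_set_collection(sets)
}

#' Simulate raw counts for a designed panel
#'
#' Draw order is fixed (lane technical factors, then per-gene baselines, then
#' lanes outer / probe classes inner) so a design with the same seed always
#' yields the same matrix.
#'
#' @param panel the `panel_definition` from [simulate_panel()] on the same
#'   design.
#' @param design a `simulation_design`.
#' @return list with elements `counts` (RAW `count_matrix`), `metadata`
#'   (`sample_metadata`), and `truth` — a list holding `log2fc` (gene x group
#'   effect matrix), `lane_factors`, `baseline_log2_means`, `enriched_sets`
#'   (spiked set names) and `affected_genes` (members actually shifted,
#'   per set).
#' @export
simulate_counts <- function(panel, design) {
  validate_design(design)
  expected <- simulate_panel(design)
  if (!identical(panel$probe_name, expected$probe_name)) {
    stop2("panel was not generated from this design")
  }
  groups <- rep(names(design$groups), times = design$groups)
  samples <- unlist(lapply(names(design$groups), function(g) {
    sprintf("%s_%d", g, seq_len(design$groups[[g]]))
  }))
  n_lane <- length(samples)
  endo <- probes_of(panel, "ENDOGENOUS")
  hk <- probes_of(panel, "HOUSEKEEPING")
  pos <- probes_of(panel, "POSITIVE")
  neg <- probes_of(panel, "NEGATIVE")

  set.seed(design$seed)
  t_j <- if (design$lane_factor_sd > 0) {
    stats::rlnorm(n_lane, 0, design$lane_factor_sd)
  } else {
    rep(1, n_lane)
  }
  b <- design$baseline_log2_means
  if (is.null(b)) {
    b <- stats::runif(length(endo) + length(hk),
                      design$baseline_log2_mean_range[1],
                      design$baseline_log2_mean_range[2])
  }
  b_endo <- b[seq_along(endo)]
  b_hk <- b[length(endo) + seq_along(hk)]
  eff <- design_effects(design)

  max_mu <- max(t_j) * 2 ^ (max(c(b_endo + apply(eff$delta, 1, max), b_hk),
                                na.rm = TRUE))
  if (is.finite(max_mu) && max_mu > 2^31) {
    stop2("simulated means exceed 2^31; shrink baseline_log2_mean_range")
  }

  conc <- panel$concentration[match(pos, panel$probe_name)]
  vals <- matrix(0, nrow = nrow(panel), ncol = n_lane,
                 dimnames = list(panel$probe_name, samples))
  draw_counts <- function(mu, phi) {
    mu <- ifelse(is.finite(mu), mu, 0)
    n <- length(mu)
    if (phi > 0) {
      out <- numeric(n)
      nz <- mu > 0
      out[nz] <- stats::rnbinom(sum(nz), mu = mu[nz], size = 1 / phi)
      out
    } else {
      stats::rpois(n, mu)
    }
  }
  for (j in seq_len(n_lane)) {
    g <- groups[j]
    mu_endo <- t_j[j] * 2 ^ (b_endo + eff$delta[, g])
    mu_endo[!is.finite(mu_endo)] <- 0
    vals[endo, j] <- draw_counts(mu_endo, design$nb_dispersion)
    vals[hk, j] <- draw_counts(t_j[j] * 2 ^ b_hk, design$nb_dispersion)
    vals[pos, j] <- stats::rpois(length(pos),
                                 t_j[j] * conc * design$pos_scale)
    vals[neg, j] <- stats::rpois(length(neg), design$background_mean)
    if (design$background_mean > 0) {
      sig <- c(endo, hk, pos)
      vals[sig, j] <- vals[sig, j] +
        stats::rpois(length(sig), design$background_mean)
    }
  }

  list(
    counts = count_matrix(vals, stage = "RAW", panel = panel),
    metadata = sample_metadata(samples, groups),
    truth = list(
      log2fc = eff$delta,
      lane_factors = setNames(t_j, samples),
      baseline_log2_means = setNames(b, c(endo, hk)),
      enriched_sets = vapply(design$spiked_sets, `[[`, character(1), "name"),
      affected_genes = eff$affected
    )
  )
}

#' The study-sized reference design
#'
#' A canned design mirroring the shape of the original orbital-disease study:
#' three groups sized 6/3/3 (an NSOI-like, an IgG4-ROD-like and a MALT-like
#' entity), a 344-probe code set (300 endogenous, 30 housekeeping, 6 positive,
#' 8 negative), and ten gene sets of size 15-40 of which three are spiked —
#' an ECM-receptor-like and an adipocytokine-like set up in the MALT-like
#' group and a cytokine-signaling-like set up in the IgG4-like group.
#'
#' @param seed RNG seed stored in the design (default 101).
#' @param log2fc effect size of the spiked sets (default 1.5).
#' @return a `simulation_design`.
#' @export
reference_design <- function(seed = 101L, log2fc = 1.5) {
  genes <- sprintf("GENE_%04d", 1:300)
  sizes <- c(30, 25, 20, 40, 15, 35, 30, 20, 25, 30)
  starts <- cumsum(c(1, sizes[-length(sizes)] - 3))  # overlapping blocks
  sets <- lapply(seq_along(sizes), function(i) {
    genes[((starts[i] - 1 + seq_len(sizes[i]) - 1) %% 300) + 1]
  })
  names(sets) <- c("ECM_RECEPTOR_LIKE", "CYTOKINE_SIGNALING_LIKE",
                   "ADIPOCYTOKINE_LIKE", sprintf("PATHWAY_%02d", 4:10))
  spikes <- list(
    list(name = "ECM_RECEPTOR_LIKE", members = sets[[1]],
         log2fc = log2fc, affected_fraction = 0.6, target_group = "MALT"),
    list(name = "CYTOKINE_SIGNALING_LIKE", members = sets[[2]],
         log2fc = log2fc, affected_fraction = 0.6, target_group = "IgG4_ROD"),
    list(name = "ADIPOCYTOKINE_LIKE", members = sets[[3]],
         log2fc = log2fc, affected_fraction = 0.6, target_group = "MALT")
  )
  simulation_design(
    n_endogenous = 300L, n_housekeeping = 30L,
    n_positive = 6L, n_negative = 8L,
    groups = c(NSOI = 6L, IgG4_ROD = 3L, MALT = 3L),
    baseline_log2_mean_range = c(5, 10),
    nb_dispersion = 0.1,
    lane_factor_sd = 0.2,
    background_mean = 5,
    spiked_sets = spikes,
    extra_sets = sets[4:10],
    seed = as.integer(seed)
  )
}
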