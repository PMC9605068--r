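---
title: "From nCounter lane counts to pathway states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From nCounter lane counts to pathway states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countpath)
```

## The problem

NanoString nCounter panels count a fixed code set of transcripts per sample
(lane) without amplification. Each lane carries, besides the endogenous
probes of interest, three control classes: positive probes spiked at known
concentrations (assay efficiency), negative probes with no target
(background), and housekeeping/reference genes (input amount). Small-cohort
studies — e.g. comparing orbital disease entities on a few biopsies per
group — need a processing chain that (i) removes lane-level technical
variation using those controls, (ii) excludes genes that cannot be
distinguished from background, (iii) compares groups with tests that do not
lean on normality in samples of three to six, and (iv) summarizes the result
at the pathway level. `countpath` implements that chain end to end, plus a
synthetic data generator that makes every stage falsifiable: patient-level
count data from such studies is typically not shareable, so the package's
evidence of correctness is built on simulations with known ground truth.

## Normalization model

For lane $j$ with positive-probe summary $P_j$ (the sum of positive-control
counts, or their geometric mean via `tech_factor_method`), the technical
factor is

$$f_j = \frac{\tfrac1L\sum_{l} P_l}{P_j},$$

and every count in lane $j$ is multiplied by $f_j$. This forces equal
positive-probe summaries across lanes — exactly the lane-efficiency
component a shared spike-in ladder can identify. The per-lane background
threshold is $b_j = \bar n_j + 2\,s_{n_j}$, the mean plus twice the sample
standard deviation (n−1 denominator) of the lane's negative probes after
technical scaling; endogenous and housekeeping counts are replaced by
$\max(x - b_j, 0)$. Negative values would be meaningless as expression and
would break the geometric means downstream, hence the clamp at zero.
Biological normalization then multiplies endogenous and housekeeping counts
by $g_j = \bar G / G_j$, where $G_j$ is the geometric mean of the
housekeeping genes usable in lane $j$. A housekeeping gene with a zero in
any lane is dropped from $G_j$ rather than patched with a pseudocount; this
keeps the post-normalization equal-geomean identity exact, which the tests
assert to 1e−9 relative. If no housekeeping gene survives, that is an error
pointing at the background subtraction — thresholds that swallow the
reference genes indicate a panel or assay problem a pipeline should not
paper over.

Finally, genes not relevantly expressed are excluded: each endogenous
gene's values across all samples are compared to the pooled negative-probe
values across all samples by a one-sided Welch two-sample t-test
(alternative: gene above negatives); genes with $p \ge \alpha$ (default
0.05) are dropped. Two readings of this filter are defensible — the test
family behind a "one-sided t-test of negative controls and target specific
counts" is not fully pinned down by convention — so Welch is the default
and the pooled-variance form is available (`var_equal`); the filter can
also be evaluated before biological normalization (`filter_stage = "pre"`)
for sensitivity analysis. Retaining the significantly-above-background
direction is the only orientation that yields a sensible filter, and is
what the package does.

The chain is ordered technical → background → biological → filter. Whether
background subtraction belongs before or after positive-control scaling is
not decidable from first principles; scaling first is the standard nCounter
workflow and is the default here, and each step checks its input stage so
the order cannot silently drift.

## Adaptive group comparison

Per gene and contrast (one entity vs the rest, or two entities pairwise):

* Shapiro–Wilk at $\alpha = 0.05$ per group decides the branch. A gene goes
  non-parametric if **any** group fails the gate — the conservative
  aggregation; groups too small (< 3) or constant to test are flagged
  non-normal rather than erroring.
* Parametric branch: two-sided pooled-variance Student t-test with a 95%
  CI of the mean difference on the normalized-count scale (CIs are only
  defined here; the rank test gets none).
* Non-parametric branch: Wilcoxon/Mann–Whitney, exact when the smaller
  group has ≤ 8 values and no ties, otherwise the normal approximation with
  tie and continuity correction. For three or more groups the same gate
  chooses one-way ANOVA vs Kruskal–Wallis (tie-corrected).
* log2 fold changes use the branch's own summary — means (parametric) or
  medians (non-parametric) — with a pseudocount (default 1) because
  background subtraction creates exact zeros.
* Benjamini–Hochberg runs over all genes of one table (the FDR family is
  the table); Benjamini–Yekutieli is available by config.

## The enrichment engine

Genes are ranked by signal-to-noise
$(\mu_A-\mu_B)/(\sigma_A+\sigma_B)$ with each $\sigma$ floored at
$\max(0.2\,|\mu|,\,0.2)$ — the floor keeps near-constant genes from
dominating the ranking — or by the log2 median ratio for a fully
non-parametric ranking. Ties break by gene name so rankings are
deterministic across platforms.

The enrichment score of a set with $k$ members in a universe of $N$ genes
is the classic weighted Kolmogorov–Smirnov running sum: walking the ranked
list, a member adds $|s_i|^w / N_R$ (with $N_R$ the sum of $|s|^w$ over
members, weight $w$ = 1 by default) and a non-member subtracts $1/(N-k)$;
the ES is the deviation of maximal magnitude, sign kept. The implementation
evaluates the walk only at member positions (the extrema can occur nowhere
else), which makes the permutation loop a matrix operation; a literal
step-by-step walk is kept in the test suite as the oracle and the two agree
to 1e−12 on random instances. Two numerical conventions worth stating: when
positive and negative extrema tie in magnitude (possible with weight 0,
where all steps are rational) the positive side wins in both
implementations; and a set whose members all carry score exactly 0 under
$w > 0$ falls back to $w = 0$ with a warning rather than dividing by zero.

The null is 1000 permutations by default. Gene-set permutation (random
member sets of the same size scored on the fixed ranking) is the default
because with three to six samples per group phenotype permutation is
severely granular — with 6-vs-6 there are only 924 distinct label
assignments, and with 3-vs-9 just 220. Phenotype mode is implemented for
larger designs and enumerates exhaustively when fewer distinct assignments
exist than permutations requested. From the null:

* $\mathrm{NES} = ES / \overline{|ES^{perm}|}$ over same-sign permutations,
  normalizing positive and negative sides separately;
* nominal $p = (1 + \#\{|ES^{perm}_{same}| \ge |ES|\}) / (1 + m_{same})$ —
  the add-one estimator, so $p$ is never exactly 0 and the $p = 0.001$
  granularity matches 1000 permutations;
* FDR $q$ by the NES-ratio method: the tail fraction of all pooled,
  normalized permuted NES beyond the observed NES over the tail fraction of
  observed NES beyond it, same sign, capped at 1, then monotonized step-up
  within each sign (each set's $q$ is the smallest raw $q$ among itself and
  every less extreme set on its side). BH on nominal p is available by
  config for comparison, but the ratio method is the convention of the
  method family and behaves better with few sets.

## Pathway projection

For each enriched set (GSEA $q \le \alpha$ by default; any named set on
request) the differential table is projected to a three-state map: UP if
log2FC ≥ +0.25, DOWN if ≤ −0.25, INDIFFERENT otherwise (undefined fold
changes land in INDIFFERENT, flagged). The 0.25 default is a deliberately
permissive reading threshold for a qualitative colour-map-style summary —
figures of this kind use continuous colour with no published cutoff — and
is recorded in every projection output so no table is ambiguous.

## What the simulator emulates — and what it does not

`simulation_design()` draws, for lane $j$ with technical factor
$t_j \sim \mathrm{LogNormal}(0, \sigma_\ell)$:

* endogenous gene $i$, group $g$:
  $\mathrm{NB}(\mu = t_j \, 2^{b_i + \Delta_{ig}}, \phi) +
  \mathrm{Poisson}(\beta)$, with variance $\mu + \phi\mu^2$;
* housekeeping genes: the same with $\Delta = 0$;
* positive probes: $\mathrm{Poisson}(t_j \cdot c \cdot
  \texttt{pos\_scale}) + \mathrm{Poisson}(\beta)$, linear in the spike
  concentration $c$ (a 128, 32, 8, … fM 4-fold ladder);
* negative probes: $\mathrm{Poisson}(\beta)$ only — independent of $t_j$
  by construction, which is precisely what makes the negative-control
  threshold meaningful and the positive-control scaling falsifiable.

$\Delta_{ig}$ is nonzero for the first $\lceil \text{fraction} \cdot m
\rceil$ members of each spiked set in its target group — deterministic
membership, so ground truth is reproducible without a second RNG stream.
Defaults: baseline log2 means uniform on [5, 10] (counts ≈ 32–1024, the
mid-dynamic range of hybridization counts), dispersion $\phi = 0.1$,
$\sigma_\ell = 0.2$ (≈ ±20% lane effects), background mean 5 counts,
`pos_scale` 30 (POS_A ≈ 4000 counts). `reference_design()` bundles the
study-shaped instance used by the analysis scripts: groups 6/3/3, a
344-probe code set, ten sets of 15–40 genes, three spiked at log2FC 1.5
affecting 60% of members. One RNG stream, lanes outer / probe classes
inner, makes a design + seed reproduce byte-identical matrices.

The simulator does **not** imitate real probe chemistry: no probe-specific
affinity, no correlation structure between genes beyond the shared lane
factor, no FFPE degradation gradient, and effect sizes are user-set rather
than estimated from any cohort. Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is correct and
calibrated under its stated model, not that any particular biological
finding would replicate.

## Numerical and testing choices

* Sample SD everywhere uses the n−1 denominator.
* Background thresholds with zero negative-probe variance degenerate to the
  mean — valid, and covered by a test.
* Completely tied groups give $p = 1$ rather than an error, so a constant
  gene cannot crash a 300-gene table.
* Exact Spearman p-values come from the reference AS89 implementation
  (exact for n < 1290 without ties); its output on an 8-point fixture was
  verified against brute-force enumeration of all 8! rank permutations.
* The hand-check value for Kruskal–Wallis on {1,2},{3,4},{5,6} is
  H = 12/42·(9/2 + 49/2 + 121/2) − 21 = 32/7 ≈ 4.571, asserted exactly.
* Problem sizes in the test suite and acceptance script: 50 random
  matrices for the normalization identities; 1000 genes for the filter's
  operating characteristics; 200 random instances for the ES oracle; 20
  seeds × 50 sets × 1000 permutations for null calibration; 20 seeds for
  recovery runs. These are the sizes at which the binomial guard bands in
  the assertions are meaningful, while a full run of everything stays in
  the minutes range on one core.
* Wall-clock timestamps are written to `run.log` only; `manifest.json` and
  all TSVs are a pure function of inputs + config + seed, so a rerun is
  byte-identical and directory digests can serve as a reproducibility
  check.

## Known limitations

* No moderated-variance (empirical Bayes) testing; with n = 3 per group the
  classical tests are honest but underpowered, and the package deliberately
  mirrors the classical-test design rather than improving on it.
* The background filter tests each gene against pooled negatives across all
  samples; a gene expressed in only one small subgroup can be excluded.
* Gene identifiers are matched case-sensitively with no alias resolution —
  silent symbol aliasing is a classic source of irreproducibility, so
  mapping is the user's responsibility (as is pinning the gene-set release
  in the GMT input).
* Phenotype permutation with tiny groups yields a very coarse p grid; the
  engine enumerates exhaustively rather than pretending otherwise, but the
  granularity is a property of the design, not fixable in software.

## A minimal run

```{r example, eval = FALSE}
design <- reference_design()
panel <- simulate_panel(design)
sim <- simulate_counts(panel, design)
cfg <- run_config(seed = 101, n_permutations = 1000)
manifest <- run_pipeline(sim$counts, panel, sim$metadata,
                         design_collection(design), cfg,
                         out_dir = "results/run")
render_report("results/run")
```
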