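---
title: "Scanning for haplotype-specific DNA methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for haplotype-specific DNA methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`hsmscan` detects methylation differences between GWAS risk and non-risk
haplotypes. The analysis unit is a 500 bp window of MeDIP-seq signal
inside the LD block of a GWAS catalogue SNP. MeDIP enrichment scales with
the count of methylated cytosines per captured fragment, so a haplotype
that carries more (or fewer) CpGs — through a CpG-SNP, a deletion, or a
repeat-length polymorphism — shifts the window score of carriers in
proportion to allelic dosage. The scan therefore tests, per window $w$
and tagging SNP $s$,

$$y_{iw} = \mu_w + \beta_w g_{is} + \gamma^\top x_i +
  u_{f(i)} + v_{j(i)} + \varepsilon_{iw},$$

where $y_{iw}$ is the rank-inverse-normal transformed RPM score,
$g_{is} \in \{0,1,2\}$ the additive allelic count, $x_i$ the covariates,
and $u_f \sim N(0, \sigma^2_f)$, $v_j \sim N(0, \sigma^2_v)$ random
intercepts for family and individual-within-family (absorbing twin pairs
and repeated time points). Unrelated cohorts drop the random terms and
reduce to OLS. The genotype term is tested by likelihood ratio against
the nested null, with both models fitted by maximum likelihood — REML
likelihoods are not comparable across fixed-effect structures — and the
statistic referred to $\chi^2_1$, since a single fixed effect is tested.

Windows that pass the Bonferroni threshold $0.05 / \#\text{windows}$ in
all three cohorts with a consistent sign of $\hat\beta$ are merged into
HSM peaks. The tri-cohort consensus, not the per-cohort threshold, is
the effective error control: a null window must clear three independent
thresholds with matching direction.

## Assumptions worth stating

- **Additivity.** Methylation responds linearly in allelic count. CNV
  deletions are the exception: a carrier of $d$ deleted copies retains
  $(2-d)/2$ of the signal, a multiplicative dosage loss rather than a
  constant per-allele shift.
- **Tagging.** The scan sees the tagging SNP, not the causal variant;
  it assumes the causal CpG-affecting variant rides the tagged haplotype
  (r² near 1). Signals attenuate as LD decays.
- **Exchangeable residuals within cohort** after covariate adjustment
  and the family/individual intercepts.

# Normalization choices

Raw window counts are scaled to reads per million, then transformed per
window across samples by the rank-based inverse normal: average ranks
$r$ map to $\Phi^{-1}\!\big((r - 0.5)/n\big)$, ties receiving the
quantile of their mean rank position. The per-window (rather than
per-sample) orientation is what a genotype association consumes: it
makes every window's response exactly standard-normal shaped, robust to
the heavy right skew of MeDIP counts, at the cost of discarding
between-window scale. A constant window cannot be ranked meaningfully;
it is set to zero and flagged low-variance, and the association engine
skips it with an explicit status rather than reporting a degenerate p.

# Coordinates

In memory every interval is a `GRanges` (1-based, closed) — the standard
container of the R genomics stack, which supplies the overlap, tiling
and merge machinery. BED conventions (0-based, half-open) are applied at
every file boundary, including the BED-style window identifiers
(`chrom:start0-end`). LD-block boundaries follow the open–closed
convention: a block runs from just after its upstream recombination wall
to and including its downstream wall base; a SNP sitting exactly on a
wall belongs to the block that ends there. Consecutive high-rate map
points collapse into a single wall, so no zero-length blocks arise.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rate_threshold` | 10 | cM/Mb | recombination rate defining block walls |
| window `size` / `slide` | 500 / 250 | bp | MeDIP fragment-scale resolution; slide = size gives the non-overlapping enrichment background |
| `alpha` | 0.05 | — | family-wise error rate before Bonferroni division |
| `min_fraction` | 0.1 | fraction | minimal overlap of a window/peak for a track hit (bedtools `-f`, inclusive, measured on the query) |
| `max_gap` | 0 | bp | peaks merge across overlapping or bookended windows only |
| probe-pruning `distance` | 0 / 10 / 50 | bp | inclusive distance from the interrogated CpG to the nearest common SNP |

# The synthetic generator

`simulation_config()` fixes the study conditions: three cohorts of
200 / 300 / 200 samples (a desk-scale rendering of a discovery /
follow-up / replication design whose follow-up set is the largest and
the only one with relatives), 20 LD blocks of 4 kb (15 windows each, 300
windows in total — small enough that the full tri-cohort scan with real
mixed-model fits runs in seconds), tagging-SNP MAF 0.3, five planted
effects of three types, residual noise SD 1 in raw score units, baseline
window mean 10, family variance 0.2 and individual variance 0.1 (a
modest familial correlation typical of blood methylation), and a
follow-up cohort composed of 40% sibling-pair samples (40% of pairs
monozygotic, sharing genotypes), 20% longitudinal repeats of discovery
individuals (sharing genotypes and individual intercepts) and 40%
unrelated singletons. Effect size κ = 1 score unit per allele gives
planted windows a variance-explained around 20–25%, deliberately strong:
the end-to-end test checks the plumbing of the scan — normalization,
mixed models, consensus, merging, annotation — not its power curve,
which `power_estimate()` measures separately.

What the generator emulates: dosage-proportional window scores,
multiplicative CNV signal loss (homozygous deletion carriers have zero
expected signal), Mendelian genotype transmission in sibling families,
genotype identity for MZ twins and longitudinal repeats, covariate
effects, and a genetic map whose walls reconstruct the simulated blocks
exactly through `build_blocks()` (a round-trip the tests exploit). What
it does not emulate: read-level sampling, fragment-length and CpG-density
coupling of MeDIP efficiency, batch-correlated noise, population
stratification, and LD decay between tag and causal variant (available
via `ld_r2`, default 1). Passing tests therefore demonstrate
correctness of the statistical machinery on data obeying the model, not
robustness to every artefact of real MeDIP cohorts.

The master seed fans out to one independent stream per cohort (plus one
for annotation fixtures), so any cohort regenerates identically in
isolation and identical seeds give byte-identical fixture files.

# Numerical choices

- The discovery engine is a vectorized Frisch–Waugh scan: scores and
  genotype are residualized against the covariate design once per SNP,
  and $\mathrm{LRT} = n \log(\mathrm{RSS}_0 / \mathrm{RSS}_1)$, which
  equals the `lm`/`logLik` route exactly; the tests pin the two paths
  together to 1e-10.
- Mixed fits use `lmer` with derivative checks off; a singular nested
  fit is refitted with a family-only intercept and flagged. When no
  grouping factor has more than one member the mixed model is not
  identifiable and the engine takes the OLS limit, flagged
  `ols_reduction` — this is exact, not an approximation, and is how the
  unrelated replication cohort runs.
- Multi-SNP blocks combine per-SNP p-values per window by arithmetic
  mean; the direction is taken from the minimum-p SNP (the mean rule
  does not define one; min-p is the natural attribution).
- Peaks splitting at direction changes keeps peaks directionally
  homogeneous; in the rare case of overlapping opposite-sign windows the
  later peak is clipped so peaks stay disjoint.
- Odds ratios use the sample estimator $(ad)/(bc)$ — which reproduces
  density-derived ratios exactly — with Haldane–Anscombe 0.5 only when a
  cell is zero, and only for the OR and its Woolf CI; Fisher's exact
  test always sees raw counts.
- Power: Monte-Carlo rejection rate of the LRT with genotypes drawn
  under Hardy–Weinberg, effect scaled so $R^2 = f^2/(1+f^2)$, checked
  against the noncentral-F closed form with $\lambda = n f^2$.

# Problem sizes

The test suite runs the full tri-cohort pipeline once at the default
configuration (300 windows × 3 cohorts, with 300-sample mixed fits for
the follow-up cohort), a 2,000-window null-uniformity check, a
100,000-window false-positive-rate check at the genome-wide threshold,
and 100-permutation array panels of 60 probes; the whole suite completes
in well under a minute on one core. These sizes were chosen so every
stochastic check has enough replicates for its tolerance while the suite
stays quick to iterate on.

# Known limitations

- The tissue-panel χ² treats base pairs as independent; when tracks are
  coarser than single bases (they always are), base pairs within a
  feature are perfectly correlated and the nominal p-values are
  anticonservative. They are reported as nominal descriptive companions
  to the fold enrichment, which is the primary panel statistic; the
  window-count Fisher tests, whose counting unit matches their
  independence assumption, are the inferential route.
- The scan is blind to effects not tagged by the catalogue SNP and to
  opposite-direction effects that cancel within a window.
- Window-level simulation cannot probe read-level artefacts (duplicate
  reads, mappability structure within a window).
- The zygosity label shapes the generative model (MZ genotype sharing)
  but adds no third variance component in the fitted model; a
  zygosity-specific environmental covariance is not modeled.
- `aggregate_multi_snp`'s mean-p combination is not a calibrated test
  statistic; it is a summary rule applied before thresholding, inherited
  by design.
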