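---
title: "Methods: from secretome profiles to prognostic gene combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from secretome profiles to prognostic gene combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secepr)
```

This vignette is the package's account of its models, its tunable
parameters, the numerical choices behind them, and what the synthetic-data
generator does and does not emulate.

## 1. Subtype-specific secretion calling

The input is a proteins x samples matrix of log2 label-free quantification
(LFQ) intensities from conditioned media of five breast cell lines — two
basal-like, two luminal, one non-malignant control — each measured in three
biological replicates with two technical replicates (30 columns).

**Row z-scoring.** Each protein row is standardized to mean 0, sd 1 over
its observed entries, using the population sd (divide by n). The
population convention makes the toy identity `z([1,2,3]) = (-1.2247, 0,
1.2247)` hold exactly and keeps z-scoring idempotent; rows with fewer than
two observed values or zero spread cannot be standardized and are dropped
with a warning rather than silently imputed.

**Missing values.** A protein is quantifiable if observed in at least
`min_valid_per_group = 3` of the 6 replicate columns of some cell line.
Imputation — drawing missing entries from a down-shifted normal (mean = row
mean − 1.8 sd, width 0.3 sd), the usual stand-in for below-detection-limit
intensities — is applied **only** before clustering, which cannot tolerate
`NA`. The ANOVA and pattern-matching stages run on observed data, so their
p-values are never flattered by imputed points.

**Reference-profile matching.** Each protein's per-cell-line mean z-vector
is matched against a profile library by Pearson correlation; the best
profile wins if r ≥ `r_threshold` (default 0.8), ties broken by library
order. The default library holds the four subtype-level profiles
(basal-up/-down, luminal-up/-down, the control line grouped with the
non-target level) *plus* one up/down profile per cancer cell line. The
single-line profiles are required: a protein elevated in exactly one
luminal line correlates with the luminal-up subtype profile at only
r ≈ 0.5 and would otherwise be unreachable, yet such one-line calls are a
real and reported class. Subtype profiles precede line profiles in the
library so a protein consistent with both resolves to the stronger
`both_lines` claim. Because Pearson correlation is location/scale
invariant, profiles are stored as 0/1 target levels and any affine
re-encoding of the library gives identical assignments.

**ANOVA validation.** Pattern matching alone performs no statistical test,
so calls are validated by a classical one-way ANOVA (equal-variance F)
across the five cell lines on log2 intensities. Technical replicates are
averaged into their biological replicate first (default), so each line
contributes 3 independent observations and technical duplicates do not
inflate the degrees of freedom; the pooled 6-per-line variant is available
(`average_tech_reps = FALSE`) since the raw-column layout is what the
z-scored heatmaps display. The default threshold is an uncorrected
p < 0.05 — this stage is a *validation filter* on pattern-matched
candidates, not a genome-wide discovery test — with an optional BH flag.

**Direction check.** A margin of `z_margin = 0.5` (mean-z units) defines
"shows the direction" line-wise: a `both_lines` call requires every line
of the subtype beyond the margin and all other lines below it; a
`one_line` call requires exactly the supporting line beyond it. The margin
blocks profile matches driven by one extreme line dragging a weak
neighbour over the correlation threshold.

**Clustering.** Heatmap ordering uses hierarchical clustering with
euclidean distance and Ward linkage on unsquared distances (`ward.D2`),
the convention under which merging two identical rows costs height 0.

## 2. SeCEP classification

For each gene in a patient cohort the two PAM50 populations — Basal vs
LumA ∪ LumB — are compared on mRNA z-scores by a two-sided
Mann-Whitney-Wilcoxon test. Her2-enriched and Normal-like patients are
excluded from this comparison (they are neither population) but stay in
the cohort for downstream screens. The exact null is enumerated when both
groups have ≤ 7 untied observations; otherwise the normal approximation
with tie and continuity correction is used. The p-values are
Benjamini-Hochberg adjusted over **all genes measured in the cohort**, not
just secretome genes: the family size is a first-order driver of the
adjusted values (tens of thousands of genes in real cohorts), shrinking
the family to a favourable subset can only shrink adjusted p-values, and
for that reason the pipeline logs the family size on every run. A
`family = "subset"` escape hatch exists for small synthetic runs.

A gene is a **basal SeCEP gene** when adjusted p < 0.05 and its median z
is higher among Basal patients, *and* (concordance, on by default) its
protein was called with *increased* secretion in basal cell lines; the
luminal case mirrors this. Genes with decreased secretion and lower mRNA
are not given a separate class — only the increased/over-expressed
direction is exercised downstream — but the discordant-yet-significant
genes are attached to the result for transparency. The working SeCEP set
is the strict intersection across cohorts: same gene, same subtype, in
discovery and validation.

## 3. Survival core

The screen needs Kaplan-Meier, log-rank and a one-binary-covariate Cox
model evaluated up to millions of times, so the package carries lean
implementations over a per-cohort precomputed sort order; the `survival`
package serves as the independent cross-check in the test suite (agreement
to ~1e-7 on the Cox coefficient, exact on KM and the log-rank chi-square).

- **KM**: product-limit estimator; censored times reduce the risk set
  without a drop.
- **Log-rank**: unweighted, hypergeometric variance, chi-square on 1 df.
- **Cox**: Newton-Raphson on the partial likelihood with Efron handling of
  ties (the default of the R function practitioners use). For a binary
  covariate every Efron term reduces to closed-form group counts, so one
  iteration is O(number of events). The 95% CI is Wald on the log scale
  with z = 1.959964, matching the screen's "lower CI > 1" criterion.
  Newton steps are damped to ±2 to avoid early overshoot; a monotone
  partial likelihood (|log HR| exceeding 15, e.g. all events in one group)
  is reported as `converged = FALSE` with the boundary direction rather
  than as an exception, and such combinations fail the CI criterion.
- Zero survival times are shifted to half the smallest positive time with
  a warning; times are otherwise used as given (months, ties allowed).

At n = 20 the exact permutation null of the log-rank statistic is
discrete, and the asymptotic chi-square p deviates from a 10,000-draw
permutation estimate by up to ~0.03 depending on where the observed p
lands; the acceptance script therefore reports the deviation averaged over
several toy data sets, which is the approximation error itself rather than
one draw's placement.

## 4. The combination screen

For a combination *G* within an analysis population (the subtype-scoped
patients with survival data), the per-gene overexpression threshold is the
median z over that population (`median_scope = "subtype"`, the default;
`"cohort"` computes medians over all patients instead — the two options
exist because either reading is defensible and the choice is logged). A
patient is altered iff strictly above threshold for every gene, so adding
a gene can only shrink the altered set, and an all-tied gene yields an
empty one.

Pass criteria per cohort: altered fraction ≥ `min_altered_fraction`
(default 0.08 for the overall-survival screen — "approximately 8%" is the
reported floor and the exact value is a required, logged configuration),
the same floor for the complement, log-rank p < 0.05, and hazard-ratio
lower CI > 1. A combination passes the screen only if it passes **every**
cohort — dual-cohort replication is the screen's error control; no
multiplicity correction is applied across combinations (an optional
BH-over-combos report exists but is off by default).

**Pruning.** Combinations failing the fraction floor in an earlier cohort
skip their survival tests and later cohorts. Because the floor is itself a
pass criterion, pruning can never change the passing set; the test suite
asserts this against a `prune = FALSE` oracle run. Enumeration is
lexicographic over the sorted gene list, results are preallocated, and
output is deterministic for a fixed input. Tests run at ≤ 20 genes;
the full-scale run (57 genes, k ≤ 5: 4,613,029 combinations per cohort) is
a documented long-running mode whose count the package computes
analytically.

**Subtype specificity.** Screens run separately per PAM50 scope (LumA,
LumB, Basal, Her2, ...) feed `subtype_specificity()`, which keeps
combinations passing in the target scope and failing in every contrast
scope. **DRFS variant**: strictly > 10% altered in both the trial and the
reference cohort, log-rank significance on the distant-relapse endpoint in
the trial cohort only; requiring reference-side significance too is an
option, off by default, because the dual-fraction/single-significance
reading is the precise one.

## 5. The synthetic-data generator

The generator is first-class, tested code; its defaults are the package's
study conditions.

| Parameter | Default | Meaning |
|---|---|---|
| `n_proteins` / `n_basal_up` | 500 / 50 | LFQ matrix size and planted basal-up proteins |
| `secretion_shift` | 1.5 | planted shift of target lines, log2 units |
| `lfq_noise_sd` | 0.4 | replicate noise sd, log2 units |
| `missing_rate`, `missing_intensity_bias` | 0.05, 1 | average missingness; logistic slope toward low intensities |
| `n_patients_by_subtype` | 150/150/150/60/40 | Basal/LumA/LumB/Her2/Normal per cohort |
| `n_genes`, `n_diff_genes`, `diff_shift` | 2000, 100, 1.0 | cohort genes; planted Basal-shifted genes; shift in z units |
| `baseline_hazard` | 0.01 /month | exponential event rate (median survival ~69 months) |
| `censor_horizon`, `dropout_rate` | 120 months, 0.5 | administrative horizon; fraction with uniform dropout |

The `secretion_shift` is expressed on the log2-intensity scale shared with
`lfq_noise_sd`: a 1.5-unit shift against 0.4-unit noise puts the planted
rows' z-profiles near +1 in basal columns, the regime in which pattern
matching and ANOVA should (and do) recover essentially all planted
proteins. Survival is exponential with hazard multiplied by the planted
hazard ratio for latent subgroup members — the simplest model satisfying
proportional hazards exactly, so Cox estimates have a clean target;
Weibull is left as an extension hook. Censoring combines an
administrative horizon with uniform dropout for a configurable fraction,
giving a closed-form event probability the tests check at n = 5000.

**Planted combinations.** For a subgroup of fraction *f* of the scoped
subtype, all combination genes are shifted jointly (the AND-mask requires
joint exceedance; independent shifts would not plant a co-overexpression
pattern) by an amount δ solved numerically: δ is the larger of the value
whose expected altered fraction equals *f* (solving the median-threshold
fixed point of the shifted mixture) and the value capturing ≥ 90% of
subgroup members jointly. The second term matters because the exact-*f*
solution can capture as little as ~75% of members — and for small
combinations (k ≤ 2 at typical *f*) the background joint exceedance
~0.5^k already exceeds *f*, so no shift attains *f* exactly; requests that
are infeasible even at δ = 8 raise an error with guidance. Consequently
the realized altered fraction tracks *f* for k ≥ 3 and overshoots it
moderately for small k.

**Sub-seeding.** Discovery and validation cohorts (and the LFQ table)
derive child seeds from the master seed by a fixed-stride counter scheme,
so adding a new table to the generator never perturbs existing ones, and
all randomness flows from one seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: gene-gene correlation outside planted
combinations (real transcriptomes are heavily co-expressed, which inflates
the effective number of discoveries), RNA-seq count noise (inputs are
ideal z-scores), batch effects, informative censoring, PAM50 label error,
and copy-number or mutation structure. Recovery rates on synthetic data
are upper bounds on real-data behaviour, not estimates of it.

## 6. Problem sizes in tests and acceptance runs

The unit suite runs at deliberately small sizes (tens of genes, hundreds
of patients) chosen so that each property is decisively powered: for
example, the end-to-end pipeline fixture uses a 250-patient Basal arm
because at 150 the dilution-adjusted planted hazard leaves the validation
lower CI hovering at 1 — a wiring test should not double as a power
experiment. The acceptance checks run at the generator's default
conditions: 2,000 genes with 100 planted for SeCEP recovery; two cohorts
of 400 Basal patients, three planted 4-gene combinations, 20 seeds for
screen recovery and for null error control; 500 proteins with 50 planted
for secretome calling. Estimator accuracy checks (Cox at true HR 2,
n = 1000) average over a few replicate draws because a single draw's
sampling noise is comparable to the tolerance being asserted.

## 7. Known limitations

- The Cox routine handles exactly one binary covariate; no multivariate
  adjustment, stratification, or time-varying effects.
- BH across combinations is reported, not enforced; the screen's error
  control is replication, which assumes cohorts are independent.
- Combination enumeration materializes each size class in memory
  (fine to k = 5 at 57 genes); a streaming chunker would be needed far
  beyond that.
- The clinical-dialect normalizer covers the cBioPortal-style columns it
  documents; other exports need renaming to the canonical columns first.
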