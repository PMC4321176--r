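---
title: "Matched two-tissue DNA methylation analysis with methmatch"
author: "methmatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched two-tissue DNA methylation analysis with methmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmatch)
```

## The problem

Population epigenetic studies usually measure DNA methylation in an
accessible surrogate tissue — peripheral blood mononuclear cells (PBMC)
or buccal epithelial cells (BEC) — and the choice matters: the two
tissues differ both in their methylation profiles and, more subtly, in
*which* CpG sites vary between individuals. When the same subjects
contribute both tissues, the matched design permits a clean separation
of between-tissue from between-individual variation, free of genetic
confounding (a methylation QTL affects both samples of a subject
equally, so paired contrasts cancel it).

`methmatch` implements the full analysis for such a matched two-tissue
cohort measured on a promoter CpG panel with beta values
(methylated fraction, in \[0, 1\]):

1. probe quality control and zero replacement,
2. probe-wise paired differential methylation with
   Benjamini–Hochberg (BH) correction, Δβ effect classes and one-way
   intraclass correlation (ICC),
3. sample-wise and probe-wise correlation structure across tissues,
   stratified by CpG-island density class (HC/IC/LC),
4. probe-wise differential variability (Levene/Brown–Forsythe on
   variance-stabilized values) with a relative variance-concordance
   band,
5. hypergeometric enrichment of probe subsets across density classes,
6. demographic association scans with Storey q-value FDR control,

plus a synthetic matched-cohort generator with a per-probe truth table,
so every stage is testable by parameter recovery even though cohort
data of this kind is rarely deposited.

## Statistical model and procedures

### Quality control

Probes are removed when they overlap a SNP, lie on a sex chromosome,
contain a polymorphic CpG, have beta values of exactly zero in more
than `n_subjects - 2` subjects in either tissue, or fail background
detection (detection p-value above 0.05) in more than 3 subjects in
either tissue. Count rules are strict inequalities: a probe with
exactly 3 detection failures is retained. Because all downstream
statistics are paired, a probe failing in either tissue is dropped from
both; the count thresholds are evaluated per tissue. After filtering,
every remaining beta of exactly zero is replaced by the smallest
strictly positive beta observed in the same tissue's matrix, so the
logit transform is defined everywhere. `n_subjects - 2` generalizes the
common "more than 23 of 25 subjects" rule to other cohort sizes while
preserving its behavior at n = 25.

### Differential methylation and tissue specificity

For each probe the per-subject differences d = β_B − β_A are tested
with the one-sample t statistic t = mean(d)/(sd(d)/√n) on n − 1
degrees of freedom, two-tailed. A *paired* test needs no
equal-variance assumption — the phrase "two-sample t-test not assuming
equal variance" sometimes attached to matched designs is internally
contradictory, and the paired form is the only coherent reading.
P-values are BH-adjusted across probes; significance is adjusted
p < 0.001. Probes are *tissue specific* when additionally |Δβ| > 0.2
(difference of tissue mean betas) and *highly tissue specific* when
|Δβ| > 0.4. Both thresholds are configurable. Degenerate inputs follow
a fixed contract: all-zero differences give t = 0, p = 1; constant
nonzero differences give an infinite statistic with the smallest
representable p-value rather than a silent NaN.

Mean methylation per probe and tissue is categorized as hypomethylated
(< 20%), heterogeneously methylated (20–80%, closed interval — the
boundary belongs to the middle class) or hypermethylated (> 80%).

### Intraclass correlation

The one-way random-effects consistency ICC with subject as the grouping
factor and k = 2 measurements per subject is

ICC = (MS_between − MS_within) / (MS_between + MS_within),

where MS_between is the between-subject mean square and MS_within the
within-subject (between-tissue) mean square. For k = 2 the value lies
in \[−1, 1\]: −1 means the between-tissue difference dominates
inter-individual spread; +1 the reverse. When total variance is zero
the ICC is undefined and reported as missing. The implementation is
tested against an explicit `aov()` ANOVA-table computation.

### CpG-island density classes

Probes are classified by the standard three-way density scheme: HC
(high density) when GC content > 0.55, observed/expected CpG ratio
> 0.75 and length > 500 bp; else IC when GC > 0.50, Obs/Exp > 0.48 and
length > 200 bp; else LC. Inequalities are strict exactly as the
thresholds are conventionally printed, and the HC rule is evaluated
first since the two rule sets overlap. Probes without island metrics
are "uncategorized": they are retained in all analyses and count
toward the enrichment population, but are not themselves a tested
category.

### Correlation structure

Within-tissue correlation is the Pearson coefficient over probes for
every unordered pair of samples in a tissue (n(n−1)/2 pairs).
Between-tissue correlation defaults to matched-subject pairs (each
subject's tissue-A profile against the same subject's tissue-B
profile); an all-pairs mode (n × n cross pairs) is available because
published descriptions often leave the pairing ambiguous, and the mode
used is recorded in the output. Between-tissue means are also computed
per density class on the corresponding probe subsets. Probe-wise
cross-tissue correlation (one coefficient per probe over the n matched
subjects) quantifies whether a subject's *relative* methylation level
carries across tissues; it receives a two-sided p from the t
transformation and Storey q-values.

### Differential variability

Beta values truncate variance near 0 and 1, so equality-of-variance
testing operates on a variance-stabilizing transform. The default is
the base-2 logit M = log2(β/(1−β)) — the M-value, the standard choice
in the methylation literature; an arcsine-square-root mode
asin(√β) is available, and the mode used is recorded in output
metadata. Either satisfies the purpose (removing the variance
truncation at the extremes); results in this package's own simulations
are insensitive to the choice.

Equality of variance per probe is tested with the classic Levene W
statistic on absolute deviations from the group center, with p from
F(1, n_A + n_B − 2). The default center is the median (the
Brown–Forsythe variant), the robust default of the common
implementations; mean-centering is a flag. BH-adjusted p < 0.05 is the
primary significance call; the unadjusted count is also reported since
descriptive summaries often quote it.

Variance concordance takes tissue A's transformed-scale variance as the
reference: a probe is within the band when var_B lies in the closed
interval \[0.8·var_A, 1.2·var_A\] (band configurable; a raw-beta-scale
mode exists for sensitivity analysis). Highly variable loci are defined
by raw beta-scale SD strictly above 0.1 or 0.3 — these cutoffs are
beta-scale magnitudes, so they are applied to raw SDs even though the
variance test runs on the transformed scale.

### Enrichment

Category enrichment of a probe subset uses the hypergeometric
distribution X ~ Hypergeometric(N, K, n) with N the analyzed
population, K the category size, n the subset size and k the observed
overlap. The direction is chosen by comparing k to its expectation
nK/N. The default tail includes the observed count (P(X ≥ k) for
enrichment, P(X ≤ k) for depletion), which is the proper one-sided
p-value; `include_observed = FALSE` gives the exclusive upper tail
P(X > k), a convention that some published analyses (including the
motivating study, judging by its printed values) used for enrichment.
No multiple-testing correction is applied across the three categories
by default; a flag enables BH. Tails are computed by `phyper()`, whose
log-space internals are numerically stable in the far tails.

### Demographic associations

Within one tissue, each probe is tested against each demographic
variable: two-sided Wilcoxon rank-sum for binary categorical variables
(sex, ethnicity), exact when the combined n is below 50 with no ties;
Pearson correlation with the two-sided t transformation for continuous
ones (age, BMI, alcohol). The effect size is the difference of group
mean betas for categorical variables; for continuous variables the
reported Δβ is the fitted beta difference between the lowest and
highest observed covariate value under the least-squares line, which
makes an "effect > 5%" filter applicable to both kinds.

FDR control uses Storey's q-value: π₀(λ) = #{p > λ}/(m(1−λ)) over
λ = 0.05, …, 0.95, smoothed with a cubic spline (df = 3) and evaluated
at the largest λ, clamped to (0, 1]; q-values follow the step-up rule
q_(i) = min_{j≥i} min(1, π₀ m p_(j)/j). For fewer than 100 p-values
the smoother is unstable, and a fixed λ = 0.5 estimate is used, which
keeps small test fixtures deterministic. With π₀ = 1 the q-values
reduce exactly to BH — a cross-method identity the test suite asserts.
The significance call is q ≤ 0.05, boundary inclusive. Because a
cohort of 25 rarely yields probe-level significance, the scan also
emits p-value distribution diagnostics (histogram at width 0.05,
fraction below 0.05, KS statistic against uniform, π₀): left skew
indicates likely association even when no single probe survives FDR.

## The synthetic cohort generator

`simulate_cohort()` generates a matched cohort with the statistical
structure the analysis assumes, plus a truth table. Values are built on
the M scale as

baseline + subject shift + tissue effect + demographic effect + noise,

then inverse-transformed to (0, 1) (clipped at 1e-6 from the bounds).

Defaults emulate a 25-subject, 998-probe promoter panel:

* **Baseline**: a three-component mixture on the M scale — 63% near
  β = 0.08, 26% near β = 0.92 (SD 0.7 each), 11% mid-range
  (SD 1.1 around M = 0) — chosen once so that default cohorts land
  near a 60/18/22 hypo/heterogeneous/hyper composition, the typical
  promoter-panel profile, and remain clearly bimodal.
* **Density classes** at 21% LC, 14% IC, 50% HC, 15% uncategorized.
* **Tissue-specific probes**: 18% of probes, |Δβ| uniform in
  \[0.2, 0.6\], sampled with 2× weight in LC (matching the field's
  repeated observation that tissue differences concentrate in
  low-density regions). Which tissue carries the shift is randomized:
  moving a probe off the beta extremes inflates its beta-scale spread,
  so a fixed choice would bias the tissues' marginal SD distributions.
* **Global offset**: tissue B exceeds tissue A by +0.02 mean beta,
  applied additively on the beta scale (a pure location shift that
  leaves each probe's spread untouched).
* **Variance structure**: a global tissue noise scale (1.10/0.90 in
  SD) makes tissue A the more variable tissue; 15% of probes are
  variance-discordant with var_B/var_A drawn from {1/3, 3}, split
  symmetrically across the two tissues so the planted ratio is exact
  and the marginal SD distributions stay unbiased.
* **Demographics**: sex 15/10, ethnicity 18/7, age uniform 26–45, BMI
  log-normal within ~18–48, alcohol Poisson(3); 50 sex-associated
  probes at Δβ = 0.15 planted in tissue B.
* **Noise**: per-probe SD log-normal around 0.35 (M scale), a small
  global per-subject shift (SD 0.10) shared across probes and tissues.
* **QC artifacts**: SNP-flagged, X-chromosome, polymorphic, zero-heavy
  (24 of 25 exact zeros) and detection-failing probes injected *on
  top* of the requested probe count, so default filtering recovers
  exactly the clean panel; a few exact zeros are also scattered into
  clean hypomethylated probes to exercise zero replacement.

The same seed reproduces a dataset byte-identically.

### What the generator does and does not emulate

It reproduces the bimodal beta landscape, LC-concentrated tissue
differences, a global methylation offset, tissue-specific variance
structure, planted demographic effects, and QC failure modes. It does
**not** simulate probe cross-hybridization, batch or plate effects,
correlated neighboring probes, mQTL genotype structure, or shared
per-probe inter-individual components across tissues — the last means
cross-tissue probe correlations are near zero for all but planted
structure, somewhat starker than real cohorts where a minority of
probes correlate across tissues. Consequently the generator also
understates cross-tissue variance concordance: with 25 subjects the
sampling noise of a variance ratio is large, so fewer probes fall
inside the ±20% band than a real cohort with partially shared
variation would show. Passing recovery tests therefore demonstrates
that the statistical machinery finds what it is supposed to find at
the study's sample size — not that real tissues behave this simply.

## Numerical and design choices

* **Percentages** print at one decimal with round-half-up (537/998 →
  53.8), matching reporting convention rather than R's banker's
  rounding.
* **Delimited I/O** is tab-separated UTF-8, "." decimal, "NA" missing;
  numeric cells are written at fixed precision so repeated writes are
  byte-identical and round-trips are exact to ~1e-10.
* **Δβ sign** is tissue B minus tissue A, with the labels taken from
  the sample sheet; reported classes use |Δβ| so the convention is
  cosmetic.
* **Hypergeometric tail convention**: the proper inclusive tail is the
  default; the exclusive upper tail is available because published
  enrichment p-values are frequently computed that way (an easy
  off-by-one with `phyper(k, ..., lower.tail = FALSE)`), and
  reproducing printed values requires matching the convention.
* **Zero-variance contracts** are explicit everywhere (see the
  function documentation) rather than propagating NaN.
* **Test problem sizes**: the suite validates calibration with 2,000
  null Levene probes and 5,000 null Pearson probes, parameter recovery
  on 20 default-size synthetic cohorts, and global-offset detection on
  200 reduced cohorts (120 probes), sizes chosen to make Monte-Carlo
  error small relative to the asserted margins.

## Known limitations

* The pipeline takes the probe universe it is given; it does not
  reconcile panel-size bookkeeping (e.g. a 1,536-probe array described
  as a 1,506-probe panel upstream of QC).
* With n = 25 the Levene test at BH < 0.05 has modest sensitivity for
  3-fold variance ratios (of order 20–35% in this package's
  simulations); the acceptance suite therefore scores it against an
  independent oracle at the realized cutoff instead of an absolute
  bar.
* An exact paired signed-rank test at n = 25 cannot produce two-sided
  p-values below 2/2²⁵ ≈ 6e-8; global contrasts reported far below
  that in the literature must come from other procedures, and no
  attempt is made to mimic them.
* Categorical association tests require binary variables; multi-level
  factors are skipped with a warning rather than recoded silently.
* No covariate adjustment or cell-type deconvolution is performed —
  the scans are exploratory, per the matched-cohort design.

## A worked run

```{r, eval = FALSE}
library(methmatch)

sim <- simulate_cohort(simulation_config(seed = 1))
run <- run_pipeline(sim$data, out_dir = "methmatch_out")
print(run)

# score the pipeline against the planted truth
truth_recovery_report(sim$truth,
                      spec_results = run$specificity,
                      variability_results = run$variability,
                      assoc = run$associations$b)
```

The README shows the printed output of this exact run.
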