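# methmatch

Analysis of matched two-tissue DNA methylation cohorts on promoter CpG
panels — the design where every subject contributes both of the two
most accessible surrogate tissues (typically buccal epithelial cells,
BEC, and peripheral blood mononuclear cells, PBMC), so between-tissue
differences, inter-individual variability and their interplay can be
separated cleanly and without genetic confounding.

`methmatch` is aimed at population epigenetics analysts who need a
tested, reusable implementation of this analysis rather than a
one-off script: every stage is a documented function on plain
data structures, with a synthetic-cohort generator and truth tables so
the whole pipeline is validated by parameter recovery.

## What it computes

For beta values β ∈ [0, 1] (methylated signal fraction per CpG and
sample):

* **Probe QC** — SNP-overlap / sex-chromosome / polymorphic-CpG
  filters, zero-prevalence and detection-failure rules (strict count
  thresholds, evaluated per tissue, dropped from both), and
  replacement of β = 0 by the tissue's minimum positive value.
* **Tissue specificity** — probe-wise paired t-test on matched
  subjects with Benjamini–Hochberg correction; tissue-specific means
  adjusted p < 0.001 and |Δβ| > 0.2, highly tissue-specific |Δβ| > 0.4;
  methylation categories (hypo < 20%, heterogeneous 20–80%,
  hyper > 80%); one-way consistency ICC per probe,
  ICC = (MS_between − MS_within)/(MS_between + MS_within) ∈ [−1, 1];
  global paired exact Wilcoxon signed-rank on per-subject means.
* **Correlation structure** — Pearson correlations over probes for all
  within-tissue sample pairs and matched between-tissue pairs, overall
  and per CpG-island density class (HC/IC/LC/uncategorized);
  probe-wise cross-tissue correlation with Storey q-values.
* **Differential variability** — per-probe range and SD per tissue;
  Levene/Brown–Forsythe test on M-values (log2 β/(1−β)) with BH
  correction; variance-concordance band (tissue-B variance within
  ±20% of tissue A); variable loci at SD > 0.1 / 0.3.
* **Enrichment** — one-tailed hypergeometric enrichment/depletion of
  any probe subset across density classes, with both the inclusive
  (proper) and exclusive tail conventions.
* **Demographics** — probe-wise rank-sum (binary variables) or Pearson
  (continuous) association scans per tissue, Storey q-value FDR, and
  p-value-distribution skew diagnostics.
* **Synthetic cohorts** — `simulate_cohort()` generates matched
  datasets with planted tissue-specific, variance-discordant and
  demographic effects plus QC artifacts, and
  `truth_recovery_report()` scores any pipeline output against the
  planted truth.

## Worked example

```r
library(methmatch)

sim <- simulate_cohort(simulation_config(seed = 1))  # 998 probes + QC artifacts
run <- run_pipeline(sim$data)
print(run)
```

```
methmatch_run: 998 probes analyzed (1056 in)
  tissue specific: 174 (17.4%), highly: 90 (9.0%)
  mean r within A/within B/between: 0.989 / 0.990 / 0.861
  unequal variance (Levene BH<0.05): 132 (13.2%); band: 169 within / 829 outside
```

58 injected artifact probes were removed by QC, leaving the 998-probe
panel. 174 probes (17.4%) pass adjusted p < 0.001 with |Δβ| > 0.2 —
the generator planted 180 — and the within-tissue sample correlations
(≈0.99) far exceed the matched between-tissue correlation (0.861),
the signature of tissue identity dominating inter-individual variation.

```r
truth_recovery_report(sim$truth,
                      spec_results = run$specificity,
                      variability_results = run$variability,
                      assoc = run$associations$b)
```

```
               effect n_true n_called  tp sensitivity specificity        fdr
1     tissue_specific    180      174 174   0.9666667   1.0000000 0.00000000
2 variance_discordant    150      132  40   0.2666667   0.8915094 0.69696970
3           assoc_sex     50       53  50   1.0000000   0.9968354 0.05660377
```

Tissue-specific and sex-associated probes are recovered nearly
completely with no or few false discoveries. The variance-discordance
row illustrates an honest limitation: at n = 25 the Levene test has
modest power for 3-fold ratios, and the generator's global tissue
variance scale makes even "concordant" probes mildly unequal, which
the truth table does not credit — see the methods vignette.

```r
run$enrichment$tissue_specific[, c("category", "overlap", "direction", "p")]
```

```
  category overlap  direction           p
1       LC      52 enrichment 0.000144003
2       IC      20  depletion 0.174360836
3       HC      75  depletion 0.004395131
```

The planted 2× LC concentration of tissue-specific probes is detected
as LC enrichment (and HC depletion) of the called set.

Single statistics are plain function calls, e.g. the upper-tail
hypergeometric probability of observing more than 51 LC probes in a
150-probe subset of a 998-probe panel with 212 LC members:

```r
hypergeom_tail(51, 212, 998, 150, "enrichment", include_observed = FALSE)
#> [1] 2.392993e-05
```

## Documentation

The methods vignette (`vignettes/matched-methylation.Rmd`) describes
the statistical model, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
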