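---
title: "Methods: integrated miRNA-mRNA differential co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA differential co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirdcx implements an integrated analysis of microRNA and mRNA expression in
small two-group tumour cohorts, of the kind profiled with a TaqMan
low-density qPCR array (a 384-well card with 377 miRNA assays and 7
endogenous controls) alongside an expression microarray. The motivating
design contrasts familial (`F-BC`) against sporadic (`NF-BC`) early-onset
breast tumours in unbalanced groups of 9 and 26 analysed samples. This
vignette records the statistical model behind each stage, the tunable
parameters and their defaults, what the synthetic cohort generator does and
does not emulate, and the numerical decisions that were genuinely open.

## CT-level quantification

Raw data are cycle-threshold (CT) values: the PCR cycle at which
fluorescence crosses a fixed threshold, so one cycle corresponds to a
factor of two in abundance and lower CT means more template.

* **Detection filtering.** A probe is excluded when the fraction of
  samples with CT above the detection limit (default 38 cycles) or an
  `Undetermined` well exceeds 0.60 *strictly, within each group
  separately* — a probe must fail in both groups to be dropped. We read
  the fraction threshold as strict (`> 0.60`) and per-group; the
  alternative reading (pooled across all samples) is a single-line change
  but is not the default. Endogenous controls are never excluded, only
  flagged, because downstream normalisation needs them.
* **Within-sample normalisation.** `delta_ct()` subtracts the endogenous
  control assay (RNU48 by default) per sample: `dCT = CT(miR) − CT(RNU48)`,
  and `2^-dCT` is linear-scale relative expression.
* **Between-sample normalisation.** `normalize_between_samples()` offers
  `median` (default in the pipeline), `quantile` and `none`, applied to
  log2 expression (`−dCT`). Median shifting is the pipeline default for a
  numerical reason: full quantile normalisation assigns every sample the
  same sorted template, so a probe that occupies the same within-group
  rank in every sample — exactly what a strong, consistent effect produces
  on a 256-probe panel — becomes *constant* within the group and its
  Pearson correlations downstream are undefined. Quantile normalisation
  remains available and tested for users with denser panels.
* **Fold changes.** The group fold change is the ratio of arithmetic group
  means of linear `2^-dCT` (not the geometric mean: the ratio-of-means
  convention matches how relative quantities are usually reported for
  these arrays) with the symmetric signed convention `r >= 1 -> r`,
  `r < 1 -> −1/r`, so no value lies strictly inside (−1, 1) and ties are
  `+1`.
* **Validation quantification.** `ddct_ratio()` implements
  `2^−(dCT(sample) − dCT(reference sample))` and `pfaffl_ratio()` the
  efficiency-corrected ratio
  `E_target^(CP_ref − CP_sample) / E_refgene^(CP_ref − CP_sample)`; the two
  agree to machine precision when both efficiencies equal 2, which the
  test suite asserts at 1e−12.

## Differential expression

**miRNAs (SAM).** For each probe the moderated statistic is
`d = (x̄1 − x̄2) / (s + s0)` with `s` the pooled standard error and `s0` a
fudge constant that stabilises low-variance probes. `s0` defaults to the
classic percentile search: candidate values are percentiles of `s`, and
the one minimising the coefficient of variation of the spread of `d`
across `s`-quantile windows is chosen; a fixed `s0` can be supplied for
reproducing a specific run (with `s0 = 0`, `d` is the ordinary pooled t
statistic, and the suite checks the rankings coincide exactly).
Significance is by delta thresholding against permutation-expected order
statistics: group labels are reassigned (exhaustively when
`choose(n, n1)` does not exceed the requested count, otherwise by
independent random draws), each permutation's sorted statistics are
averaged into `d̄(i)`, and features beyond the first crossing of
`|d(i) − d̄(i)| ≥ delta` are called. The study's operating point is
`delta = 0.77` with achieved FDR 0. The FDR estimate is the median number
of permuted statistics beyond the cut points divided by the number of
calls, 0/0 defined as 0, with the `pi0` correction available but off by
default (the permutation count and `s0` of the original run are not
recoverable, so the defaults are our own: 1,000 permutations).

**mRNA probes (permutation t-test).** Pooled-variance t per probe with a
group-label permutation p-value. Sampled permutations use the add-one
estimator `p = (1 + #{|t*| ≥ |t|}) / (1 + N)` so p is never zero;
exhaustive enumeration (which contains the observed labeling) reports the
exact tail fraction. Zero-variance probes are stabilised by flooring the
pooled variance at the 5th percentile of the positive pooled variances.
Probes significant at `P ≤ 0.01` are collapsed to unique genes; the gene
direction is that of its most significant probe and genes with
conflicting probe directions are flagged rather than resolved.

## Discriminant classification

`fit_lda()` is a two-class Fisher discriminant:
`w ∝ S⁻¹(μ1 − μ2)` with `S` the pooled covariance, assignment by
comparing `w·x` to the prior-adjusted midpoint. Features are z-scored on
the training samples (dCT scales differ across assays); priors default to
the training class frequencies because the design is deliberately
unbalanced (9 vs 26), with an equal-prior mode available. When `S` is
singular a ridge of `1e-6 · trace(S)/p` is added and recorded on the
model. Leave-one-out cross-validation refits the model — including the
standardisation — on each training fold of `n − 1` samples and reports
per-group accuracies, the honest counterpart of the resubstitution
accuracy, which is also reported together with the misclassified sample
identifiers.

## Target-list integration

Target predictions are inputs, not queries: a flat table of
(miRNA, gene) pairs with the number of supporting prediction algorithms
and five boolean stringency criteria carried as metadata (seed-region
complementarity, cross-species conservation, duplex thermodynamic
stability, multiple sites, central loop). Stringency is expressed as the
minimum number of supporting algorithms (default 3; 1 is the lenient
mode) since the exact query settings behind any given export are not
recoverable. Candidates are the case-insensitive intersection of the
differentially expressed genes with the predicted target sets of the
differentially expressed miRNAs; no alias resolution is attempted.

## Differential co-expression

This is the package's core statistic. For each (miRNA, gene) pair the
Pearson correlation is computed separately within each group on
log2-scale normalised expression (correlating heavy-tailed linear
`2^-dCT` values is unstable; a linear mode simply means passing linear
tables), and the observed statistic is the absolute correlation
difference `Δr = |r1 − r2| ∈ [0, 2]`. The null distribution reassigns the
samples to two groups of the *original* sizes, without replacement,
independently each iteration — 100,000 times at the study's operating
point — and each pair is compared with its own permutation distribution
(never a pooled null). The p-value is one-sided on the upper tail, as
`Δr` is non-negative by construction; sampled permutations use the
add-one estimator and exhaustive enumeration the exact tail fraction. A
permutation in which a pair's correlation is undefined (a constant
vector) is excluded from that pair's null count and tallied in
`n_invalid`. No multiple-testing correction is applied beyond the stated
`P < 0.05` threshold, matching the original analysis.

Significant pairs are classified into four categories by prediction
status and fold-change signs: `predicted_inverse` (prediction plus
opposite signs, the pattern expected of repressive post-transcriptional
regulation), `predicted_same`, `unpredicted_inverse`,
`unpredicted_same`. Sign is taken from the log ratio, so a tie fold
change of +1 counts as `same`. Percentages are reported to one decimal;
because published tables in this literature mix truncation and rounding,
both conventions are implemented (`half_away` default, `truncate`
alternative) and the summary records which was used. Classified pairs are
exported per group as bipartite GraphML plus a flat edge list: node size
is the absolute signed fold change, edge weight the correlation
magnitude, edge sign and category carried as attributes.

## The synthetic cohort generator

There is no deposited raw CT matrix for this design, so the package
ships a generator whose defaults *are* the study conditions: a 377-probe
panel with 7 controls, 35 samples in groups of 9 and 26, 121 probes
planted below detection (leaving 256), nine differentially expressed
miRNAs with the published fold magnitudes (six up, three down), 91
differentially expressed genes (57 up, 34 down) and 20 planted
differentially co-expressed pairs (`paper_scale_preset()`).

The CT model is Gaussian on the cycle scale:
`CT = baseline − log2(fold) + N(0, sd)` with per-probe baselines uniform
on 22–32 cycles and a noise standard deviation of 0.5 cycles, a typical
replicate SD for these cards. Because CT is a log2 quantity, a planted
fold of `m` shifts the affected group by `log2 m` cycles and the ratio of
group means of `2^-dCT` recovers `m` in expectation; the suite verifies
recovery of a planted 4.28-fold within ±10% at 200 samples per group.
Controls are generated at a quarter of the probe noise SD, reflecting
the stability that justifies their use for normalisation. Below-detection
probes draw CT uniformly on 38.5–40 in every sample, and a configurable
fraction of those wells (default 0.3) is emitted as the literal
instrument token `Undetermined` — both encodings must survive the reading
and filtering path, and do.

Differential co-expression is planted through a latent factor shared
with the miRNA: within each group the partner gene's log2 value is
`mean + shift + sd · (r·z + sqrt(1 − r²)·ε)`, where `z` is the miRNA's
standardised realised log2 expression in that group. This conditional
construction gives population correlation exactly `r` with no attenuation
from measurement noise, and lets one miRNA anchor several pairs (each
gene carries at most one pair). Requesting `|r| = 1` with non-zero CT
noise is rejected as infeasible. Clinical tables are drawn per group from
the frequency profile of the motivating cohort, with subtypes derived
from the drawn receptor calls so records are internally consistent.

What the generator does *not* emulate: probe-specific amplification
efficiencies, cross-hybridisation, batch or card effects, heavy-tailed or
censored CT noise, and correlated gene-gene backbone structure. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated model, not robustness to every artefact of real TLDA
data. The noise model itself (Gaussian on CT) is our choice; instrument
noise models are not published for this card.

## Numerical choices and degenerate inputs

* Permutation p-values: add-one for sampled permutations, exact tail
  fraction for exhaustive enumeration (the identity labeling keeps p
  positive). Comparisons use a 1e−12 absolute guard against floating ties.
* Constant vectors make Pearson correlation undefined; they propagate as
  `NA` (observed) or are dropped from the null with a tally (permuted).
* A single master seed fans out to per-stage child seeds as
  `(seed + 7919·k) mod (2^31 − 1)`, so any stage can be re-run in
  isolation and the whole pipeline is byte-reproducible.
* `fisher.test` backs the 2×2 association test in the clinical module;
  the suite cross-checks it against a direct hypergeometric enumeration.
  A table with an empty margin returns p = 1.

## Problem sizes used by the suite

The bundled tests and the acceptance script run, among smaller toys: the
full 377-probe preset cohort through filtering, SAM (1,000 permutations)
and LOOCV; a 500-pair null calibration and a 200-pair power study, each
at 2,000 permutations over groups of 10 and 25. These sizes give
Monte-Carlo standard errors small enough for the calibration band
(0.03–0.07 at alpha 0.05) and the 0.8 power threshold while keeping the
whole suite in the tens of seconds on one core; the 100,000-permutation
operating point remains the default of `pipeline_config()` for real
analyses.

## Known limitations

* The detection-filter wording ("more than 60% of the samples in both
  groups") is interpreted per-group and strictly; cohorts filtered under
  the pooled reading can differ at the margin.
* The discriminant stage assumes a shared within-group covariance;
  with 9 samples in the smaller group the estimate is noisy, which is
  why features are pre-selected by the DE stage and standardised.
* Published accuracy figures for small-cohort discriminant analyses can
  disagree with the misclassification counts they accompany (82% vs 32/35
  in the motivating study); the package reports both the accuracy and the
  misclassified identifiers and never forces agreement.
* Interaction classification depends on fold-change signs estimated from
  small groups; pairs near a tie fold change are sensitive to the
  normalisation method.
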