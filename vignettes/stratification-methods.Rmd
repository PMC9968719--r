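---
title: "Stratifying AML cohorts from phosphoproteomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying AML cohorts from phosphoproteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhosphoStrat)
```

PhosphoStrat stratifies leukaemia cohorts from phosphoproteomic intensity
matrices and connects the resulting subgroups to kinase activities and ex
vivo drug response. This vignette is the package's own account of the
models it implements, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic-cohort tests do and do not establish about real data.

## Data model

All intensity layers (phosphopeptides, proteins, PTM peptides, mRNA) are
`OmicsMatrix` objects: `SummarizedExperiment`s with one `log2intensity`
assay, feature annotations in `rowData` and per-sample metadata in
`colData`. Missing measurements are `NA` and are never imputed at the IO or
normalization layer; each statistic declares its own missing-data policy.
Normalization is per-sample median-centering (`normalizeIntensities()`),
which zeroes each column's observed median exactly and preserves
within-column differences. This is a deliberately simple stand-in for
whatever upstream batch normalization a real quantification pipeline
applies; the package assumes its input is already comparable across
samples and centres.

Quality control (`applyQC()`) consumes pre-computed boolean flags
(`mislabelled`, `high_rbc`, `high_tcell`, `low_viability`) rather than
inventing cytometry cut-offs; `flagQC()` derives flags from user-chosen
thresholds. A sample with several flags is excluded once but counted under
each reason, which is why per-reason counts can exceed the number of
excluded samples in a cohort report.

## The stratification procedure

`stratifyCohort()` composes five stages, all of which draw information from
the training split only:

1. **Feature selection.** Per-feature unpaired two-sided Student's
   *t*-test (pooled variance) between the positive class (KMT2A-rearranged)
   and the rest of the training samples. Features are ranked by ascending
   p-value, with ties broken by larger |log2 FC| and then feature id so the
   selection is fully deterministic. The signature keeps the top
   *k* = ⌊*n*~train~/2⌋ features — selecting half as many features as
   training samples to limit overfitting — unless the user overrides *k*.
2. **PCA.** The signature submatrix of the training samples is
   feature-centered and decomposed with `stats::prcomp` (unscaled). Missing
   cells are imputed with the training-set feature mean, a constant that is
   stored and reused when projecting new samples, so projection never moves
   information backwards.
3. **Region definition.** The positive-class training samples are
   hierarchically clustered in (PC1, PC2) with Euclidean distance and Ward
   linkage (`ward.D2`), and the tree is cut into two clusters. Procedures
   of this kind are usually described only as "hierarchical cluster
   analysis"; Ward on the first two components is the standard choice for
   compact subgroup splitting and is exposed as is. The larger cluster defines the subgroup
   region: its convex hull, expanded outward from its centroid by a margin
   of 5 % of the PC1 range. The margin is the one transparent knob that
   decides how borderline samples fall; collinear or coincident clusters
   degrade to a margin-thickened rectangle or square rather than a
   degenerate polygon.
4. **Region labelling.** Training samples inside the region (boundary
   inclusive, by an explicit on-segment test) are labelled MLLGA, the rest
   No-MLLGA.
5. **Classification.** A 1000-tree random forest is trained on the
   signature submatrix with the region labels and reclassifies every
   sample; the vote fraction is the reported probability and ties at 0.5 go
   to MLLGA. The classifier output is the authoritative final label — a
   borderline sample near the region edge can legitimately be pulled inside
   by the forest. Out-of-bag accuracy is reported, and feature importances
   (mean decrease in Gini impurity, normalized to sum to 1) rank the
   signature.

The no-leakage property — selection, centering, region and forest are
functions of the training samples alone — is asserted by a test that
perturbs every non-training sample and requires bit-identical model state.

## Differential statistics and enrichment

`ttestTwoGroup()` implements the classic pooled-variance *t*-test row-wise
over observed values, with Welch as a toggle. Features with fewer than
`minObs` (default 3) observations in either group are reported as untested
rather than given a p-value; the threshold is exposed because real
phosphoproteomics matrices are sparse and any silent default would change
counts. Degenerate rows (both groups constant) get *t* = 0, *p* = 1 when
the means agree and ±Inf, *p* = 0 otherwise — a convention that matters for
noiseless simulated screens. Counting rules (`countSignificant()`) use
strict inequalities (*p* < 0.05, |log2 FC| > 0.8 or 0.7), matching the
wording of the thresholds they implement. Set enrichment
(`enrichSets()`) is a one-sided hypergeometric upper-tail test with BH
adjustment across sets; it deliberately does not reproduce any web-tool
"modified Fisher" EASE correction — the exact test is fully specified and
reproducible, which the web tool is not.

Benjamini–Hochberg adjustment is `stats::p.adjust(method = "BH")` behind a
validating wrapper. Note that step-up BH is not idempotent: re-adjusting an
adjusted vector generally changes it, so the package's tests assert the
true invariants (monotonicity in sorted-p order, `fdr >= p`, equality with
an independent step-up computation) instead.

## KSEA

Kinase activity for a kinase with *m* observed substrates and substrate
scores S is `z = (mean(S) - mean(all)) * sqrt(m) / sd(all)` — the mean
substrate deviation from the global score distribution in standard errors —
with a two-sided normal p-value and BH across kinases. Per-sample mode
scores each sample's row-centered log2 intensities (deviation from the
feature's cohort mean); per-contrast mode scores a log2 fold-change vector.
Kinases with fewer than `minSubstrates` (default 3) observed substrates
are reported but not scored. The z-score form is fixed as the package's
single KSEA variant; the union of all features scores exactly zero, the
statistic is invariant to adding a constant to every feature, and strictly
increasing in any substrate's score — all asserted as properties.
Substrate sets are consumed at phosphopeptide-feature granularity via GMT;
mapping site-level databases onto quantified peptides is the caller's
responsibility.

## Dose-response curves and DSS

Percent inhibition is anchored to the plate controls:
`100 * (vehicle - signal) / (vehicle - positive)`, so DMSO wells sit at 0
and full-kill positive controls at 100; a plate whose vehicle mean does not
exceed its positive-control mean is rejected as dead. The fitted model is a
four-parameter log-logistic in log10 molar concentration,
`y = bottom + (top - bottom) / (1 + 10^(slope * (log10ic50 - x)))`,
least-squares fitted with bounded Levenberg–Marquardt from a fixed grid of
12 starting points (four IC50 guesses crossed with slopes 0.5/1/2.5).
The grid matters: with 5-point curves, single-start fits land in boundary
local minima on roughly a tenth of cases, while the grid brings the
noiseless round-trip error to numerical precision (the package asserts
1e-3 relative recovery). Bounds are bottom ∈ [-10, 50], top ∈ [0, 120],
slope ∈ [0.2, 10], IC50 within three decades of the dose window; the
`converged` and `atBound` flags are honest and a monotone-decreasing
response (impossible under the rising parameterization) is recorded, never
silently smoothed.

DSS integrates the fitted curve above an activity threshold *t* (default
10 % inhibition) over the tested log10 dose window using the closed-form
4PL antiderivative (with an overflow-safe `log1p` evaluation), normalizes
by the maximal attainable area `(100 - t) * (x2 - x1)` (DSS1), and
optionally discounts by the curve top (DSS2, the default), clipping to
[0, 100]. A flat zero curve scores exactly 0 and a saturated curve scores
DSS1 = 100. The score is monotone in potency and in `-t`, both asserted
against fine-grid trapezoid integration. Which DSS variant and threshold a
given published screen used is rarely stated; both are parameters.

Proliferation is reported exactly as the screening convention prints it:
`ratio = (day0 / day3) * 100`, so *faster* growth gives a *smaller* ratio.
Because that orientation is easy to misread, `growth_fold = day3/day0` is
emitted alongside (documented as not the screening statistic;
`ratio * growth_fold = 100` identically). Proliferation stratification
thresholds at the arithmetic mean of a reference group, ties going to
"High pro".

## Correlation analyses

Spearman rho is the Pearson correlation of midranks. For n ≤ 9 complete
pairs the two-sided p-value is exact — computed over all n! permutations —
because the t-approximation is poor exactly where ex vivo cohorts are
small; above that the usual `t = rho * sqrt((n-2)/(1-rho^2))`
approximation applies. Missing data are handled pairwise-complete per
cell, with the pair count reported; cells under `minPairs` (default 5) are
untested, not errors. Correlation matrices default to per-test
significance masks (no adjustment), matching how correlation-plot crosses
are usually reported; BH within drug rows is available. The
`correlatedSets()` extraction (significantly positive / negative features
for a drug) feeds the hypergeometric enrichment.

## The synthetic cohort generator

`simulateCohort()` draws log2 intensities as feature baseline
(`N(22, 2)`, a typical MS dynamic range whose location is irrelevant to
every downstream statistic) plus group effects plus `N(0, noiseSd)` noise,
then removes entries completely at random. The planted structure mirrors
the study design the package targets: a named number of samples per group
(default 8 MLLGA, 4 MLLGB, 20 No-MLL, 4 Normal — a desk-scale cohort with
the same shape as a two-centre poor-risk AML collection), 18 planted
signature features at +2 log2 in MLLGA over 0.5 log2 noise, kinase
substrate sets of 10 with a planted +1 log2 CDK1 shift in MLLGA (echoing
the elevated mitotic-kinase activity such subgroups show), and a screen
where 3 of 24 drugs gain one decade of potency in MLLGA. Centre
(BCI/FIMM), train/validation/verification splits and KMT2A fusion-partner
labels are assigned per group so that the training split always contains
both contrast classes. Missing-value rates and intensity distributions are
not published quantities; the defaults (5 % MCAR) are explicit config
fields, and an intensity-dependent missingness toggle exists but is off by
default because no missingness model is given for the data the package
emulates.

The screen simulator emits raw luminescence wells: vehicle and
positive-control wells per sample plate (full-kill floor, CellTiter-Glo
convention), drug wells following the 4PL with per-sample IC50 jitter, and
untreated day-0 wells so proliferation can be estimated; MLLGA samples
grow 3-fold in 3 days versus 2-fold for other AML and 1.5-fold for donors.
One seed drives every draw, so a cohort is reproducible as a unit, and the
generator records its ground truth (planted features, kinases, drug
potencies, true groups) for parameter-recovery tests.

What passing these tests shows: the pipeline recovers planted structure of
realistic magnitude under Gaussian noise and MCAR missingness, its
statistics are calibrated under the null, and each numerical component
agrees with an independent implementation. What they do not show: robustness
to batch effects, intensity-dependent missingness, heavy-tailed intensity
noise, plate spatial artefacts, or biological correlation between features —
real phosphoproteomes violate feature independence, and the generator makes
no attempt to model that.

## Problem sizes and runtime

The shipped tests and the acceptance script run cohorts of 22–36 samples
with 300–2000 features, 5–150 kinase sets and 5–24 drugs; the full suite
takes well under a minute on one core. These sizes were chosen because
every planted-recovery property is already decisive there; all generators
scale to larger cohorts by config alone.

## Known limitations

- The KSEA variant is fixed to the mean-enrichment z-score; delta-count
  variants are out of scope.
- The region geometry (convex hull + margin) and the two-cluster Ward cut
  are one concrete realization of a loosely specified procedure; both are
  config knobs.
- DAVID-style EASE-corrected enrichment is intentionally not reproduced.
- `stratifyCohort()` takes splits from metadata verbatim; it does not
  audit how the user built them.
- Survival analysis of the resulting groups and drug-combination scoring
  are out of scope.

```{r example}
cohort <- simulateCohort(simulationConfig(
  nPerGroup = c(MLLGA = 6L, MLLGB = 3L, `No-MLL` = 10L, Normal = 3L),
  nFeatures = 400L, nSignatureFeatures = 8L, nKinases = 5L, seed = 7L))
model <- stratifyCohort(normalizeIntensities(cohort@omics$phospho),
                        cohort@metadata, seed = 7L, nTrees = 300L)
table(predicted = assignments(model)$label,
      truth = cohort@truth$groups)
```
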