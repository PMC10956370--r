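---
title: "Methods: ancillary-feature screening and category adjustment for LR-3/4 liver lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancillary-feature screening and category adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liradsaf)
```

## The model in brief

A liver observation in a patient at high risk for hepatocellular carcinoma
(HCC) is described by three binary major features (MFs: nonrim
arterial-phase hyperenhancement, nonperipheral washout, enhancing capsule),
its diameter, sixteen binary ancillary features (AFs), and the contrast
agent used (hepatobiliary vs extracellular — the transitional and
hepatobiliary phases, and hence three of the AFs, exist only with the
former). The pipeline has four stages:

1. **MF categorization.** The v2018 decision table maps (APHE, size bin,
   washout, capsule) to LR-3/LR-4/LR-5. Size bins are left-closed at 10 and
   20 mm, matching integer-millimetre reporting. Threshold growth is not
   modeled: growth AFs need a follow-up window the cohort design excludes,
   so at 10–19 mm with APHE a single extra feature reaches LR-5 only via
   washout; capsule alone gives LR-4.
2. **AF screening.** For each AF, a 2×2 table against the group label is
   tested (Fisher's exact test when any expected cell < 5, else Pearson
   chi-square without continuity correction) and the odds ratio of the
   feature in the non-HCC group over the HCC group is estimated with the
   Woolf interval. Features with univariable Wald p < 0.10 enter a forward
   stepwise search with likelihood-ratio entry at the same threshold; the
   selected AFs are split into malignant/benign by prevalence direction.
   Two contrasts are screened: all lesions (panel label AF-HCC) and the
   LR-3/4 stratum only (AF-LR).
3. **Adjustment.** Among LR-3/4 lesions: only malignant panel AFs present →
   upgrade one step, capped below LR-5 (an upgraded LR-4 lesion keeps its
   category but is recorded as upgraded — required for the outcome counts to
   be interpretable, since upgrades exceed the LR-3 pool); only benign →
   degrade one step (a degraded LR-3 becomes LR-2, terminal here); both or
   neither → retain.
4. **Evaluation.** Sensitivity = upgraded / HCC LR-3/4 lesions; specificity
   = not-upgraded / non-HCC LR-3/4 lesions. Between two panels: Cohen's
   kappa on the three-level outcome labels and McNemar tests (exact
   binomial below 25 discordant pairs, else uncorrected chi-square;
   Bonferroni factor 2 across the sensitivity/specificity pair). Screened
   logistic models are internally validated with a stratified 7:3 split,
   Mann–Whitney AUC with Hanley–McNeil intervals, equal-width calibration
   bins, and decision-curve net benefit.

## What the synthetic generator emulates — and what it does not

No lesion-level dataset is public for this design, so `sample_cohort()`
draws cohorts that reproduce the published *marginal* structure: group
sizes 311/162, per-feature prevalences, diameter-bin frequencies
(uniform within bins; the ≥20 mm bin spans 20–80 mm, consistent with a
mean lesion size near 33 mm), and per-group hepatobiliary-agent fractions
(98/302 and 40/158).

Three structural constraints are honoured during sampling:

* **Exclusive pairs.** Mild–moderate and marked T2 hyperintensity (and HBP
  hypo- vs isointensity) cannot co-occur. They are drawn jointly with zero
  co-occurrence and both marginals preserved — one uniform draw partitioned
  into the two probability strata. Clearing one member of a conflicting
  pair after independent draws would bias the commoner feature's
  prevalence by up to ~0.11.
* **Phase-dependent AFs** are drawn only among hepatobiliary-agent lesions,
  at the conditional probability `p / agent_fraction` that restores the
  specified marginal.
* **Joint infeasibility.** The published marginals for the HBP pair in the
  non-HCC group (24/162 + 27/162) exceed the hepatobiliary-agent stratum
  (~41 of 162 lesions), so no cohort can satisfy all three constraints at
  once. The generator proportionally rescales that one pair;
  `target_prevalence()` reports the attainable marginals, which equal the
  specification everywhere else. Convergence is property-tested at
  n = 10,000 per group (all attainable marginals within 0.02).

Features are otherwise sampled **independently** within group. Real imaging
features co-occur (a large infiltrative HCC tends to show several
malignancy AFs at once), which has two visible consequences on synthetic
cohorts: stepwise selection is *easier* than in clinical data (independent
signals carry non-redundant information), and the upgrade rule fires more
often in both groups, raising sensitivity and lowering specificity relative
to the published clinical values. Passing recovery tests therefore shows
the screening machinery works, not that clinical operating points are
reproduced. A Gaussian-copula variant (`sample_cohort_correlated()`, single
latent severity factor with configurable loading) is provided to make
recovery experiments harder and more realistic; patient-level clustering
(2–3 lesions per patient) is not modeled.

`marginal_fixture()` serves the opposite purpose: a deterministic cohort
whose per-feature per-group counts equal the printed table *exactly*, for
contingency-level unit tests. Its joint structure (features assigned to
deterministic blocks of lesions) is an arbitrary artifact; it is unsuitable
for model fitting, and its agent mix deviates from the specification
because every phase-AF-carrying lesion must receive the hepatobiliary
agent.

## Numerical choices

* **Logistic regression** is Newton–Raphson/IRLS with convergence declared
  on the score (max |gradient| < 1e-8, cap 100 iterations). Separation —
  routine with sparse AFs such as mosaic architecture, absent in one group
  — is flagged (any |beta| > 15, or a singular information matrix) and
  returned as a non-converged fit rather than an error; separated
  candidates are skipped by the stepwise search and excluded by the
  univariable filter (their Wald p collapses toward 1).
* **Confidence intervals** use the exact 97.5% normal quantile
  (`qnorm(0.975)` = 1.959964); with the rounded 1.96 one published bound
  differs in the second decimal.
* **Zero cells** in odds-ratio tables get the Haldane–Anscombe 0.5 added to
  all four cells, flagged `corrected`; the group-comparison test handles
  sparsity by the expected-count rule instead.
* **Entry statistic.** The univariable filter uses the Wald p (matching how
  separated features behave in published univariable columns); stepwise
  entry uses the likelihood-ratio test, which is better behaved near
  separation. Both thresholds default to 0.10, and
  `bypass_univariable_filter` lets a user reproduce designs where a feature
  with a null univariable p still enters multivariable modeling.
* **Stratified split** determinism: per-class train counts are
  `floor(n_class × f)`, with the remainder to reach `round(n × f)` assigned
  by descending fractional part; for 311/162 at 0.7 this gives 218 + 113.
  Which rows fill the quota is the only seeded choice.
* **Ties** in AUC scores are handled by midranks (equivalently, half-credit
  for tied case–control pairs); stepwise ties break by candidate order.

## Design decisions that were genuinely open

* **Odds-ratio orientation.** Only with odds of the feature in the non-HCC
  group over the HCC group do the published benignity-direction
  univariable estimates equal the frequency-table cross-products (28.29,
  12.24, 10.48, 0.17, 0.12); the malignancy-direction rows match no
  orientation of the printed marginals and are not used as oracles. The
  screening response is accordingly coded y = 1 for non-HCC.
* **Specificity definition.** The principled complement of "upgraded" is
  used: non-HCC lesions *not upgraded*. The published specificity values
  correspond to retain+upgrade counts, which is not a standard definition;
  they are treated as unrecoverable rather than imitated.
* **Degrade from LR-3** goes to LR-2 (the one-step principle); the outcome
  label, which is what all downstream statistics consume, is unaffected.
* **Upgraded LR-4 stays LR-4** but records the upgrade outcome; the
  published outcome distribution (113 upgrades among 133 HCC LR-3/4
  lesions, more than the LR-3 pool alone) forces this reading.

## Problem sizes

The test suite and the acceptance script run the stochastic checks at the
sizes where their targets are statistically stable: prevalence convergence
at 10,000 lesions per group; panel-recovery and method-agreement runs on
cohorts at 4× the study's group sizes over 10 seeds; the designed
two-informative/eight-noise selection experiment at 500 lesions per group.
The between-method kappa on such cohorts is typically 0.62–0.68 —
substantial agreement, qualitatively echoing the clinical finding — and
the train/validation AUC gap of the screened models averages well under
0.05 across seeds, though single seeds fluctuate by the sampling noise of
a few-hundred-lesion validation set.

## Known limitations

* Marginal fidelity only: no empirical joint distribution of AFs exists to
  calibrate against, so absolute sensitivity/specificity on synthetic
  cohorts differ from clinical values by construction.
* The multivariable odds ratios of the clinical study are not reproducible
  from printed marginals; the pipeline's multivariable estimates are
  internally consistent but not comparable row-by-row.
* Inter-reader agreement (ICC) is out of scope — it requires two-reader
  data that is not tabulated per lesion.
* LR-M, LR-TIV and the benign LR-1/2 diagnostic pathways are not modeled;
  LR-2 exists only as the degrade target of LR-3.
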