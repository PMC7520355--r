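---
title: "Methods: evaluating AI-assisted cytology against manual reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating AI-assisted cytology against manual reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervscreen)
```

This vignette documents the models and design decisions behind
`cervscreen`: how the slide score is built, what the dual-arm
partial-verification protocol implies for the statistics computed on top of
it, what the synthetic cohort generator does and does not emulate, and the
numerical choices a maintainer would want written down.

## The slide score

Each slide carries per-cell prediction scores in [0, 1]. The slide score is
an exponentially rank-weighted mean of the top `M` cells:

$$S = \frac{\sum_{m=1}^{M'} e^{-m} S_{(m)}}{\sum_{m=1}^{M'} e^{-m}},
\qquad M' = \min(M, \#\text{cells}),$$

with $S_{(1)} \ge S_{(2)} \ge \dots$ the cell scores in descending order and
ties broken by stable input order. Two decisions are worth stating
prominently:

* **Ranking.** The weights $e^{-m}$ decay so fast (the first cell carries
  63% of the total weight, the first three 95%) that the aggregate only
  makes sense if $S_{(m)}$ is the $m$-th *largest* score: the most
  abnormal-looking cells dominate, and $S$ behaves like a softened maximum.
  This matches a screening display that surfaces the twenty highest-scoring
  image patches. An unranked reading of the same formula would make $S$
  depend on arbitrary input order, which no screening device could intend.
* **Default `M` = 20**, matching those twenty displayed patches. `M` is a
  parameter because the slide-level formula itself does not pin it down;
  with the default cell-score distributions the choice barely matters
  beyond $M \approx 5$ (weights below $e^{-5}$ are < 1% of the total).

A slide is reported normal when $S < 0.5$. Only "less than 0.5" defines
normality, so the boundary $S = 0.5$ is classified abnormal. Slides with
fewer than 5000 epithelial cells are unsatisfactory (reason
`too-few-cells`, which dominates in practice), as are slides with stacked
cells, an obscured background, or scant cellularity; unsatisfactory slides
are excluded from every analysis set.

The mapping from an abnormal $S$ to a specific Bethesda grade is *not*
defined by the scoring model; in simulation it is delegated to the reader
model below, never to a score cut-point table.

## The protocol and its partial-verification structure

`apply_protocol()` implements the study flow: all AI-abnormal slides get a
manual reading plus a simple random sample (default fraction 0.10) of
AI-normal slides; a woman graded ASC-H, LSIL or HSIL by either available
arm is referred to colposcopy; histology exists only for attenders.
ASC-US triggers interim rescreening, not referral — so ASC-US lives below
the referral threshold throughout the accuracy analysis.

Two consequences shape every statistic downstream:

* **Severity vs display order.** The paired table stores grades in display
  order NILM, ASC-US, ASC-H, LSIL, HSIL, but clinically ASC-H sits with
  LSIL above the referral line. All thresholding uses the severity ranking
  (`grade_severity()`), so "LSIL+" means {ASC-H, LSIL, HSIL}. This set, and
  only this set, reproduces the published sensitivities.
* **Partial verification.** Women negative in both arms are never biopsied,
  so disease status is unknown for them. The accuracy construction
  (`assemble_accuracy_set()`) follows the study: verified women plus the
  *concordant-normal* block — women graded NILM by both arms, counted
  disease-negative without verification and screen-negative in both arms.
  Sensitivity is estimated only among *detected* cases; cases missed by
  both arms never enter the denominator, so the estimate is biased upward
  relative to the readers' true operating characteristics. The package
  makes this bias measurable rather than hiding it: with
  `verify_all = TRUE` the protocol reveals histology for everyone, and the
  test suite demonstrates both that full verification recovers the
  generative sensitivities and that the partial design inflates them
  (at the default configuration, from roughly 90% truth to about 99%).

The random 10% review sample is an unstratified simple random sample; the
source protocol says only that selection was spread over the programme's
stages, and nothing in the analysis depends on stratification.

## Agreement and accuracy statistics

* **Kappa.** $\kappa = (P_o - P_e)/(1 - P_e)$ with identity weights or
  linear weights $w_{ij} = 1 - |i-j|/(k-1)$. Linear weights on the stored
  five-grade order reproduce the published weighted kappa of 0.92; the
  value is insensitive to swapping ASC-H/LSIL into clinical order (0.9199
  vs 0.9172, both rounding to 0.92), which the tests assert as a
  regression guard. Quadratic weights are deliberately not offered as a
  default because nothing in the source analysis requires them. The SE is
  the asymptotic non-null (Fleiss–Cohen–Everitt) formula; the kappa CI
  method of the source report is unstated, so printed kappa intervals are
  not asserted anywhere.
* **Per-grade kappas** are unweighted Cohen's kappa on the one-vs-rest 2×2
  collapse, which reproduces all five published values
  (0.93/0.87/0.76/0.88/0.83).
* **Agreement-rate CIs** are Wald by default (these reproduce the printed
  94.5–94.8), with Wilson behind a flag for small tables.
* **Detection-rate CIs** are Clopper–Pearson exact binomial intervals —
  the natural reading of "exact method" for a binomial proportion.
* **McNemar** defaults to the uncorrected $(b-c)^2/(b+c)$; the continuity
  correction is available. With $b + c = 0$ the p-value is 1.
* **Difference CIs** for sensitivity/specificity are independent-samples
  Wald intervals, which reproduce every printed interval; a
  discordant-pair (paired) interval would be narrower but does not match
  the published analysis, so it is not the default. Published difference
  *points* subtract rounded percentages, so a recomputed difference can
  sit 0.05 off the printed one (e.g. 4.45 vs a printed 4.5).
* **Paired odds ratios** use an in-package logistic GEE with exchangeable
  working correlation and robust sandwich variance; women are clusters and
  contribute one observation per arm that assigned them the grade. Under an
  independence working structure with singleton clusters it reduces exactly
  to ordinary logistic regression (asserted to 10⁻⁶ in the tests). The
  published age-adjusted odds ratios themselves are *not* reproducible —
  individual ages were never released — so the estimator is validated on
  synthetic data with known truth instead, and the published values serve
  only as context.
* **Cluster-aware prevalence** treats screening sites as primary sampling
  units with a between-cluster linearised variance and reports the design
  effect. A single cluster falls back to binomial variance with a warning.

## The synthetic cohort generator

The generator exists so that the whole pipeline can be tested end to end
with known truth. Each woman gets an age group, a screening site, a latent
histology state, an adequacy draw, and two grades.

* **Latent states**: healthy, cervicitis (biopsy-confirmed negative —
  distinct from healthy because only biopsied women can receive it), CIN1,
  CIN2, CIN3, cancer. Defaults: cervicitis 1.2%, CIN1 0.25%, CIN2 0.05%,
  CIN3 0.115%, cancer 0.014%. These are *illustrative* values chosen once
  so that the implied anchors match the programme's printed figures
  (abnormal cytology ≈ 4.9% split 3.4/1.2/0.3 across
  ASC-US/LSIL/ASC-H+HSIL, expected CIN2+ yield ≈ 155 per 100,000,
  referral fraction ≈ 1.5%); no age-specific prevalences were published,
  so the age profile is a smooth monotone multiplier (0.45–1.45 across the
  five age bands, normalised against the age distribution).
* **Readers** are 6×5 confusion matrices P(grade | state). Disease-state
  rows follow the empirical grade distributions of verified lesions; the
  healthy rows are *solved analytically* from the target marginal grade
  distribution, so the expected margins of the default configuration equal
  their targets exactly (`expected_profile()` returns them in closed
  form, including the expected CIN2+ yield via a bivariate-normal orthant
  probability). Note the cervicitis row is estimated from *referred*
  cervicitis women, which overstates how abnormal an average latent
  cervicitis slide looks; this is absorbed into the choice of its
  prevalence and documented rather than corrected.
* **Correlation between arms** uses one shared latent uniform per woman
  through a Gaussian copula (default ρ = 0.9), spanning independence to
  perfect agreement with a single parameter instead of a joint 6×25
  confusion object.
* **Sites** enter as a random intercept (SD 0.3, log-odds scale) on the
  disease-state probabilities only, making cluster-robust prevalence
  intervals testably wider than binomial ones while leaving the
  healthy-dominated grade margins essentially uninflated.
* **Age** affects latent prevalence only, not reader error — there is no
  published information on age-dependent reader accuracy, and adding it
  would create an unidentifiable knob.
* **Cell mode** (`ai_mode = "cells"`) generates per-cell scores instead of
  drawing the AI grade directly: normal cells from Beta(2, 50), plus
  1 + Poisson(25) abnormal cells from Beta(8, 2) on slides with a
  non-healthy latent state; cell counts are log-normal
  (median 9000, σ = 0.3155, putting 3.1% of slides under the 5000-cell
  adequacy threshold). With these defaults the aggregated slide
  classification agrees with the latent abnormal state on ≥ 99% of slides,
  so the reader-mode and cell-mode pipelines are interchangeable for
  downstream statistics.

What the generator does **not** emulate: images and segmentation, HPV
status, treatment, the 6–12-month interim round (a single baseline round
only), inter-cytologist heterogeneity within the manual arm, and
age-dependent reader accuracy. Passing tests therefore show that the
*statistics* are correct under the stated generative assumptions — not
that the generative assumptions describe any particular real population.

## Numerical and testing choices

* All randomness flows through explicit seeds; the simulator and protocol
  save and restore the caller's RNG state, so identical seeds give
  byte-identical cohorts and the caller's stream is never perturbed.
* Probability vectors must sum to 1 within 10⁻¹²; reader rows within 10⁻⁸
  (then renormalised exactly).
* The GEE clamps the working correlation to (−0.99, 0.99), uses the
  analytic inverse of the exchangeable correlation matrix, and runs a
  fully vectorised path for cluster sizes ≤ 2 (the paired-arm case) that
  is asserted equal to the general per-cluster loop. Fully concordant
  arms leave a robust variance of exactly zero; a floating-point hair
  below zero is clamped before the square root.
* Degenerate inputs: empty tables, margins concentrated in one category
  (κ undefined), zero discordant pairs (p = 1), zero detection
  denominators, and single clusters all raise errors or documented
  fallbacks rather than returning NaN.
* Calibration checks in the test suite run at n = 200,000 simulated women
  with 3-standard-error (binomial or Monte-Carlo) bands; the end-to-end
  sensitivity-recovery checks use the same cohort size, which leaves
  roughly 350 CIN2+ cases and keeps the whole suite under half a minute.
  These sizes were chosen as the smallest giving stable 3σ verdicts for
  rates of order 10⁻³.
* Fixture integrity is re-validated on every load (margins, equal arm
  totals per histology stratum, component sums); any mismatch aborts with
  a data-integrity error. The programme's three circulating totals
  (703,103 enrolled / 701,301 eligible / 703,301 in a figure caption) are
  shipped as-is with provenance notes; prevalence denominators follow the
  convention of each published figure. The concordant-normal block is
  63,209 (the accuracy-table footnote), not the 63,233 concordant-NILM
  cell of the paired table; the 24-woman gap (attendance loss among
  manually upgraded AI-normals) is surfaced by
  `evaluate_reference_study()` rather than silently reconciled.

## Known limitations

* Sensitivity/specificity inherit the verification bias of the design;
  the package quantifies it in simulation but cannot remove it from
  fixture-based estimates.
* The GEE supports the exchangeable and independence working structures
  only — sufficient for paired-arm data, not a general GEE replacement.
* Kappa CIs use the asymptotic SE; no bootstrap, and no multi-rater
  (Fleiss-type) generalisation.
* The simulator's defaults are calibrated to aggregate anchors, not fitted
  to record-level data; treat absolute simulated quantities (e.g. the
  CIN2+ yield) as scenario values with Monte-Carlo and specification
  uncertainty.
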