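---
title: "Spectral-CT arterial enhancement fraction markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-CT arterial enhancement fraction markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraef)
library(dplyr)
```

## The clinical problem

Thyroid micronodules (up to 10 mm) are common incidental findings, and most
are benign. Deciding which of them to biopsy is the practical question: every
false positive is an unnecessary invasive procedure. Dual-layer spectral CT
acquires high- and low-energy data in a single pass, so alongside the
conventional blended 120-kVp-equivalent image it yields virtual
monoenergetic images (40-100 keV), iodine-density maps and effective
atomic-number maps for each contrast phase. `spectraef` implements the
marker derivations and the complete diagnostic-evaluation chain for this
setting, driven by a synthetic-cohort generator so that every stage is
testable without scan data.

## The markers

For each nodule, with arterial phase (AP) and venous phase (VP)
measurements:

* **Spectral curve slope** `lambda_HU = (HU_40keV - HU_100keV) / 60`
  (HU/keV), per phase. Iodine attenuates disproportionately at low keV, so
  the slope indexes iodine content.
* **Normalized iodine concentration** `NIC = IC_nodule / IC_carotid` and
  **normalized effective atomic number** `NZeff = Zeff_nodule /
  Zeff_carotid`, per phase, where the same-phase carotid-artery value
  removes inter-scan contrast-timing variability.
* **Arterial enhancement fraction**, two routes to the same physiological
  quantity (how much of total enhancement arrives in the arterial phase):
  - blended single-energy images:
    `AEF_S = (HU_a - HU_u) / (HU_v - HU_u)` from the non-contrast (u),
    arterial (a) and venous (v) attenuation;
  - iodine maps: `AEF_D = IC_a / IC_v`.

Malignant micronodules, with their immature and inefficient vasculature,
show delayed enhancement and relative venous iodine retention: lower AEF,
lower arterial slope, lower arterial NIC/NZeff. Orientation therefore
matters in the ROC analysis and is auto-detected from cohort medians
(malignant median below benign implies `lower_is_malignant`), with a manual
override available, since the state-direction choice is an explicit input of
any ROC computation.

## The synthetic-cohort generator

No per-nodule data accompany the study the defaults emulate; the generator
reproduces its *published summaries*: per-marker `median (Q1, Q3)` by
cohort, and categorical frequencies (calcification, enhanced blurring, age,
sex), at the study's cohort sizes of 131 benign and 190 malignant nodules.

**Marginals.** Each positive, right-skewed marker is modelled log-normally.
A `median (Q1, Q3)` summary inverts in closed form: `mu = log(median)`,
`sigma = log(q3/q1) / (2 z_0.75)` with `z_0.75 = qnorm(0.75) = 0.6745`. This
matches the median exactly and the quartile *ratio* exactly; when the
published quartiles are not symmetric about the median on the log scale the
absolute IQR is only approximated, which is the price of a two-parameter
family. A gamma family would fit equally well but has no closed-form
median/IQR inversion.

**Derived-first construction.** Marker values are drawn first, then raw
per-phase fields are back-filled so derivation reproduces the drawn values
exactly (machine precision): the 100 keV attenuation sits at a 60 HU
soft-tissue baseline with the 40 keV value set from the drawn slope; the
blended-image enhancement span `HU_v - HU_u` is fixed at +60 HU (the benign
worked example's span is 79.7 HU; a fixed positive span keeps the `AEF_S`
denominator far from the unstable regime); arterial carotid iodine sits at
5 mg/mL (a typical arterial-phase carotid value, and the scale on which the
published normalized concentrations are plausible absolute
concentrations), carotid Zeff at 10. Because `AEF_D = NIC_a / NIC_v` would
over-determine the iodine fields if both carotid references were pinned,
the venous iodine is set from the drawn `AEF_D` and the venous carotid
reference from the drawn `VPNIC` - all three marginals then hold
simultaneously.

**Dependence.** By default the two AEF markers share a Gaussian copula on
the log scale with correlation 0.75, which reproduces a pooled rank
correlation near the published 0.71 without claiming knowledge of the
study's joint law; `copula_rho = NULL` gives full independence. All other
markers are independent - real spectral parameters are surely correlated
(all partly measure iodine), so simulated *combinations* of markers are
optimistic relative to real data, and combination AUCs from this generator
should be read as upper bounds. Single-marker results depend only on the
marginals and are faithful.

**What passing tests show.** Distribution recovery, determinism and
round-trip exactness validate the generator and derivations; single-marker
AUC recovery validates the ROC machinery against the published
discrimination. They do not show that real nodule data would reproduce the
study's multivariable coefficients or combined AUCs, which depend on the
unpublished joint distribution.

**Patient versus nodule.** Age and sex frequencies were published per
patient (107/183 patients) while the pipeline operates per nodule (131/190
nodules); with no published patient-to-nodule mapping, the frequencies are
applied per nodule.

## Statistical procedures

* **Normality gate.** Continuous comparisons test each cohort with the
  Kolmogorov-Smirnov statistic under estimated parameters, i.e. the
  Lilliefors correction (the naive KS p-value with estimated mean/sd is
  anti-conservative), plus Levene's variance-homogeneity test; the pooled
  t-test is used only when all gates pass at 0.05, otherwise Mann-Whitney.
  Groups below 5 observations skip the (undefined) gates and use the rank
  test directly.
* **Mann-Whitney.** Exact two-sided p by exhaustive enumeration of group
  assignments of the pooled mid-ranks for combined n up to 20 (ties handled
  exactly); beyond that, the tie-corrected normal approximation without
  continuity correction, matching common clinical-statistics software at
  cohort scale.
* **Categorical tests.** Pearson chi-square without continuity correction
  when all expected counts are at least 5, otherwise Fisher's exact test
  (Freeman-Halton for 2x3). Note the rule is about *expected* counts: the
  published calcification table has an observed cell of 3 but all expected
  counts above 5, so chi-square applies.
* **Agreement.** Bland-Altman bias, SD of differences and limits of
  agreement `bias ± 1.96 SD`, with the difference direction fixed as
  `AEF_S - AEF_D` (benign medians 1.436 vs 1.259 make the published
  positive bias consistent with this order). Spearman's rank correlation is
  the headline coefficient per the methods convention; Pearson's r is
  reported alongside.
* **Logistic regression.** Maximum likelihood via IRLS (`stats::glm`),
  predictors entered untransformed (a published odds ratio of 0.600 per
  unit of the arterial slope is only meaningful unstandardized).
  Forward selection is the "Forward: LR" analog: entry by
  likelihood-ratio p < 0.05, removal at p > 0.10. Quasi-complete separation
  aborts with guidance rather than returning divergent estimates. VIFs come
  from auxiliary ordinary-least-squares regressions on the raw predictor
  matrix - a linear collinearity side-analysis, which is how clinical
  packages report VIF next to logistic models.
* **ROC.** The AUC is the tie-corrected pairwise probability
  `(#concordant + ½ #ties) / (n_m n_b)`, identical to the trapezoidal area
  under the empirical ROC (the suite verifies the identity to 1e-12).
  Confidence intervals use DeLong placement-value variance (the de facto
  standard where no method is stated) with Wald limits truncated to [0, 1].
  Cutoffs maximize Youden's J over midpoints between consecutive distinct
  scores plus the infinite endpoints; ties favor sensitivity (screening
  convention), then the lower oriented cutoff. Calcification enters ROC
  analysis ordinally as absent (0) < macro (1) < micro (2), the coding under
  which the published AUC and sensitivity/specificity pair are exactly
  reproduced from the contingency counts; the Youden maximizer is then the
  any-calcification split.
* **Unnecessary biopsy rate.** `FP / n_benign = 1 - specificity` at the
  operating cutoff - the study's clinical-utility metric, reported from the
  same confusion table as the rest of the panel.

## Numerical choices and degenerate inputs

* `AEF_S` denominators below `epsilon = 1` HU (sub-noise venous minus
  non-contrast differences) yield `NA` with an `unstable_denominator` flag;
  flagged records are excluded from downstream stages with a logged count.
  Negative `AEF_S` is legitimate (arterial below non-contrast attenuation),
  retained unclipped, and flagged.
* Derived markers are stored at full precision; two-decimal AEF display and
  one-decimal percentages are applied only at report time.
* IRLS convergence tolerance 1e-8, at most 100 iterations; every fit's
  score equations are checked in the suite.
* A marker with more than 20% missing values is refused rather than
  silently evaluated.
* Constant samples: normality returns statistic 1 / p 0; correlations on a
  constant vector are refused (or reported `NA` inside Bland-Altman);
  single-valued score vectors give a degenerate cutoff with J = 0.

## Worked example

```{r worked-example}
derive_markers(worked_example_records()) |>
  select(nodule_id, cohort, aef_s, aef_d) |>
  mutate(across(c(aef_s, aef_d), ~ round(.x, 2)))
```

The benign nodule retains most of its enhancement in the arterial phase
(AEF_S 1.58, AEF_D 1.40); the malignant one enhances late (0.90, 0.93).

## A full synthetic run

```{r pipeline}
report <- run_pipeline(default_cohort_spec(seed = 20260928))
report
```

Problem sizes throughout the package's examples and tests are chosen to be
statistically decisive at desk scale: the study-sized cohort (321 nodules)
for pipeline runs, 200 replicates for AUC recovery, 2,000-4,000 replicates
for type-I-error calibration, and 10^5-10^6 draws where a Monte-Carlo
quantile check needs two-decimal resolution.

## Known limitations

* Cross-marker dependence beyond the AEF copula is not modelled; combined
  models on synthetic cohorts overstate real incremental value.
* The generator produces nodule-level records only - no patient clustering,
  no scanner batch effects, no images (ROI measurement is a mean-under-mask
  stand-in).
* In-sample evaluation only, as in the study design: no cross-validation or
  train/test split, so combination AUCs carry optimism.
* No multiple-testing correction in the comparison table (the evaluation
  chain applies none).
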