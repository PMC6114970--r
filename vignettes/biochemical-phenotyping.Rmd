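---
title: "Metabolite-ratio biochemical phenotyping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-ratio biochemical phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboratio)
```

## The problem

Targeted plasma metabolomics panels of the p180 class report absolute
concentrations (μmol/L) of 186 analytes spanning acylcarnitines, amino
acids, biogenic amines, hexoses, phosphatidylcholines,
lyso-phosphatidylcholines and sphingomyelins. In metabolic-disease and
oncology cohorts the informative quantities are usually not single
analytes but *ratios*: a quotient of a product and substrate concentration
is a crude but robust proxy for the activity of the enzyme connecting
them, and it cancels global scaling (hydration status, calibration drift)
that inflates single-analyte variance. This package encodes a working
vocabulary of such ratios — glutaminolysis (Gln/Glu and derivatives),
hepatic function (Fischer's quotient and variants), fatty-acid-oxidation
and CPT-2 screening ratios, desaturase/elongase indices, arginine
methylation, glycolysis proxies, and composite discriminants — and the
statistics used to evaluate them as biomarkers.

## The panel model

`panel_schema()` fixes a canonical roster: 40 acylcarnitines, 21 amino
acids, 19 biogenic amines, 1 hexoses channel, 38 + 38 PCs, 14 lysoPCs,
15 SMs (186 core), plus an optional 5-analyte energy extension (Lac, the
combined pyruvate/oxaloacetate channel `Pyr`, alpha-KG, Fum, Suc) that is
only present in some cohorts; catalog entries needing absent analytes are
retained but marked unavailable rather than silently dropped. The exact
roster of a p180-style kit varies slightly by vendor generation; the class
counts are the fixed constraint, and two membership choices were made to
keep the published ratio vocabulary expressible at those counts: Total DMA
is computed as ADMA + SDMA rather than carried as a 20th amine channel,
and PC ae C32:3 (required by the GCKR proxy PC aa C42:0/PC ae C32:3) is
included among the 38 acyl-alkyl PCs. The schema JSON export makes all
membership decisions auditable, including the nine-essential amino-acid
convention used for the Essential/Non-essential sums.

Concentrations are nonnegative or missing; missingness is an explicit
mask, never zero. Input zeros are treated as below the limit of detection
and converted by policy — the default replaces them with half the
per-analyte minimum positive value, the common metabolomics convention,
because keeping zeros would detonate every ratio with that analyte in the
denominator. `keep` and `missing` policies are available where a study
prefers them.

## The ratio catalog

Each of the 96 definitions is a finite expression tree over analyte
symbols with two operators, sum and quotient. The evaluator propagates
missing leaves and maps zero denominators to missing-with-reason, so no
feature is ever ±Inf. Each definition carries a *concentration degree*
(leaf = 1; sums preserve degree; quotients subtract): degree-0 features
such as Gln/Glu, Fischer and Lac/Pyr are invariant to rescaling all
concentrations by any c > 0, while degree-d features scale as c^d. The
test suite checks both laws on randomized inputs, which guards against the
most common transcription error in hand-entered equations (an unbalanced
numerator).

Three readings of ambiguous printed forms are fixed here and documented:
the signature denominator token `C102` is read as the decenoyl-carnitine
C10:2; `Phe/(Gln/Glu)/Asp` is parsed as Phe / [(Gln/Glu)/Asp] because the
bracketed composite is defined elsewhere as a unit; and `AcylC-DC` is read
as the sum of dicarboxyl (-DC) acylcarnitines. The SFA and MUFA sums are
derived mechanically from the name parser — acyl-alkyl PCs with more than
36 carbons and 0 (SFA) or 1 (MUFA) double bonds — because the defining
rule, not the roster, is what is stated. The two liver-index variants of
the breast-cancer signature are both provided: `val_phe` (default) and
`xle_phe`, with Xle taken as the combined Leu+Ile signal since leucine and
isoleucine are isobaric in this assay class.

## Evaluation machinery

All statistics operate on natural-log features (concentrations are
right-skewed and strictly positive after LOD handling).

* **Univariate screening** uses Welch's t for two groups and one-way ANOVA
  beyond, with Benjamini–Hochberg FDR across tested features. BH is the
  procedure meant by "FDR calculation" in common metabolomics pipelines;
  the implementation is cross-checked against a brute-force oracle on an
  exhaustive grid of short p-vectors.
* **ROC/AUC** uses the midrank (Mann–Whitney) statistic, so ties split
  evenly, and a threshold-sweep curve whose trapezoidal area equals the
  statistic exactly. The operating point maximizes Youden's J; ties break
  toward higher specificity. No rule is standard here, and Youden is the
  least arbitrary single choice when sensitivity and specificity are
  reported as a pair.
* **MCCV** draws, per iteration, a class-stratified subsample of 2/3 of
  each class for training ("balanced subsampling", read as proportional
  stratification without replacement), fits the classifier — including its
  per-feature standardization — on the training fold only, and scores the
  held-out third. The default classifier is ridge-penalized logistic
  regression (glmnet, α = 0, λ = 0.01): a linear model preserves the
  semantics of a two-feature discriminant, is deterministic, and avoids
  importing an external web service's SVM/RF stack; a 2-component PLS-DA
  (via mixOmics) is available as an option. λ = 0.01 on standardized
  features is small enough to leave a strong two-feature signal
  essentially unshrunk while keeping separable folds finite.
* **Permutation testing** re-runs the full MCCV under label permutations
  and applies the add-one convention p = (b+1)/(N+1), so the smallest
  attainable p at N = 1000 is ≈ 1e-3. Published permutation p-values far
  below 1/(N+1) (e.g. 2e-5 from 1000 permutations) can only come from a
  parametric tail approximation; this package reports the empirical
  convention only.
* **Bootstrap CIs** for the AUC resample cases and controls independently
  (percentile interval), which also makes degenerate single-class
  resamples impossible.
* **The univariate logistic risk model** is fit by maximum likelihood;
  under (quasi-)perfect separation it warns and returns a ridge-penalized
  estimate instead of divergent coefficients.
  `reference_logistic_model()` packages the published Lac/Pyr model
  logit(P) = −12.24 + 1.80·x; note exp(1.80) = 6.05 while the published
  odds ratio is 6.08, consistent with a slope of ≈1.805 rounded before
  printing — the printed coefficients are stored verbatim.
* **Hierarchical clustering** uses Ward linkage (`ward.D2`) on Euclidean
  distances of autoscaled features, the de-facto standard for
  metabolomics heatmaps; the linkage/distance pair is a documented choice,
  not a published one. Distances fall back to pairwise-complete values
  under missingness.

All stochastic operations take an explicit seed and restore the caller's
RNG state; nothing reads or leaves global state.

## The synthetic-cohort generator

No cohort data are deposited for the study design this package serves, so
the generator is the test bed. Marginals are lognormal — concentrations
are positive and right-skewed — parameterized by an arithmetic control
mean and CV per analyte, with independence across analytes. Defaults
encode the published quantities: control Gln 800 μmol/L with a case
multiplier of 1/8; control Glu 40 and Asp 2.5 with 10× case elevations;
Phe 57 → 89.3. Direction-only case markers (taurine, Met-SO, SM C18:0,
PC ae C38:3, lysoPC a C26:1, C14:1-OH, PC aa C36:6 up; C10:2 down;
PC aa C28:1 shifted up) default to 2× or 0.5× and are tagged
`invented_direction_only` in the provenance map, as are the ~170 control
means without a published value (set to class-typical healthy-plasma
levels). The common CV defaults to 0.25, a typical biological
between-subject spread for plasma metabolites; below-LOD injection
defaults to 1% of cells.

The case lactate mean is calibrated in closed form rather than searched:
the ratio of two independent lognormals with common CV is lognormal with
median equal to the ratio of the arithmetic means and
sdlog = sqrt(2·log(1+CV²)), so the Lac multiplier solving
P(Lac/Pyr > 25.8) = 0.76 is
`25.8 · exp(qnorm(0.76)·sdlog) · mean(Pyr)/mean(Lac)` ≈ 1.65.

`simulate_continuum()` interpolates the case multipliers geometrically
(mean_g = control_mean · multiplier^λ) across an ordered grade ladder —
metabolic-syndrome grades 0–5, relative-risk grades 1.4/1.6/1.8, in-situ,
invasive — with λ from 0 to 1, mirroring the observed monotone drift of
Gln/Glu and related proxies from health to invasive disease. The λ values
are evenly spread; only their order and endpoints are meaningful.

**What passing tests do and do not show.** The generator reproduces group
means, fold-changes, the Lac/Pyr exceedance rate and lognormal spread; it
does not reproduce inter-analyte correlation (analytes are independent
within a group), batch effects, assay drift, or covariate structure (age,
BMI, menopausal status). Consequently within-group correlation estimates
on synthetic data are null by construction, and discriminant performance
on synthetic cohorts speaks to the *pipeline's* correctness — given
effects of the published size, the machinery recovers them at the
published operating characteristics — not to expected performance on new
clinical samples. The near-ceiling AUCs on synthetic data are what the
printed effect sizes mathematically imply: the five analyte shifts in the
signature equation compound multiplicatively into a ~12-fold median case
shift against a ~0.55 log-scale SD.

## Numerical and degenerate-input choices

Zero denominators and missing leaves yield missing values with recorded
reasons, never exceptions or infinities. Zero-variance features in the
screen get p = 1 with a warning rather than NA, so downstream FDR vectors
stay aligned. MCCV requires ≥3 samples per class so the stratified split
leaves at least one held-out sample per class; classifier standardization
guards zero-SD features; an all-constant training fold scores at the
training prevalence. ROC ties follow the midrank convention (all-equal
scores give AUC = 0.5). Problem sizes in the test and acceptance runs —
cohorts of 31/59 and 169/154, 100 MCCV iterations, 10 seeds, n = 1000
calibration draws — are the study's own design sizes, with permutation
counts reduced in unit tests where only the counting convention is under
test.

## Known limitations

* The 186-name roster is a reconstruction constrained by the class
  counts; a lab using a different kit generation should pass its own
  schema (`normalize_analyte_names()` will map dialects onto it).
* Independence across analytes is the generator's strongest
  simplification; correlated blocks (e.g. within lipid classes) would be
  the natural extension.
* Essential/non-essential amino-acid membership, the Xle channel, and the
  AcylC-DC sum are documented interpretations of under-specified printed
  definitions.
* The permutation test is exact but expensive (it re-runs MCCV per
  permutation); for large N users should lower `n_iterations` in the
  null re-evaluations, which is the configuration default exposed.
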