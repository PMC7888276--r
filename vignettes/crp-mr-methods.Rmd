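---
title: "Methods: one-sample Mendelian randomization of CRP on time-to-breast-cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample Mendelian randomization of CRP on time-to-breast-cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpmr)
```

## The problem and the estimand

Observational associations between circulating C-reactive protein (CRP) — a
marker of chronic low-grade inflammation — and postmenopausal breast cancer
are confounded by lifestyle and prone to reverse causation, because
preclinical tumours themselves raise CRP. Mendelian randomization (MR) uses
genetic variants that raise CRP as instrumental variables: alleles are
assigned at conception, so a genetically predicted exposure is free of
classical confounding and reverse causation, provided the instruments act on
the outcome only through the exposure.

The estimand throughout is `theta`, the log hazard ratio of incident
invasive breast cancer per unit increase of the exposure — per unit of
natural-log CRP (mg/L) for instruments discovered against continuous CRP, or
per unit log-odds of chronic inflammation (CRP > 3.0 mg/L) for instruments
discovered against the binary inflammation status. The two instrument
classes are **never pooled in one estimator run**; `mr_onesample()` fits
them separately and labels each result with its exposure scale.

## The analysis chain

1. **Instrument curation** (`qc_filter`, `prune_ld`, `merge_studies`,
   `exclude_pleiotropic`, `orient_effect_alleles`). Variants are retained
   when the missing-call rate is < 2%, the 1-df Hardy–Weinberg chi-square
   p-value is >= 1e-4, and imputation quality R² is >= 0.6 (variants without
   an imputation record count as genotyped). LD pruning is greedy: variants
   are ranked by |gamma/se| and accepted when the squared dosage correlation
   with every accepted variant is below 0.3. "LD < 0.3" does not name a
   metric; we use r², the conventional pruning statistic, with ties broken
   by variant id so the output is deterministic. Records duplicated across
   source studies are harmonised by allele flip where needed and collapsed
   to the most recent publication (ties: smallest standard error).
   Instruments tagged for obesity, glycaemic or lipid traits can be
   excluded, since those traits open pathways to breast cancer that bypass
   CRP. All effects are oriented so the effect allele is CRP-raising.

2. **Per-variant outcome effects** (`fit_cox_per_snp`,
   `fixed_effect_meta`, `snp_outcome_scan`). Each variant's log hazard
   ratio per effect-allele dosage comes from a Cox proportional-hazards
   model, fit separately within each genotyping sub-study and pooled by
   fixed-effect inverse-variance meta-analysis. Stage 1 adjusts age and 10
   genetic principal components; stage 2 additionally adjusts 15
   lifestyle/demographic covariates (education, income, family history,
   CES-D depressive score, cigarettes/day, MET-h/week physical activity,
   alcohol g/day, % calories from saturated fat, age at menopause, and
   durations of OC, E-only and E+P use, plus height, weight and
   waist-to-hip ratio). The published count of "15 variables" does not
   decompose uniquely from the prose; this is the set we fix and document.
   Ties use the Efron approximation (Breslow available). Separation or
   non-convergence yields a flagged estimate with an infinite-SE sentinel
   that pooling skips — this keeps pooled estimates well defined and
   auditable. Proportional hazards is checked per variant as the Pearson
   correlation between the dosage term's scaled Schoenfeld residuals and
   the rank of event times, with its correlation-test p-value.

3. **Summary-statistic estimators** (`mr_fit`). With per-instrument
   exposure effects `gamma_j` and outcome effects `Gamma_j`, the Wald
   ratios `b_j = Gamma_j / gamma_j` are combined by:

   * **IVW** — `sum(w_j b_j) / sum(w_j)` with `w_j = 1/se_j²`,
     `SE = sqrt(1/sum(w_j))`; identical to weighted least squares of
     `Gamma` on `gamma` through the origin. Fixed-effect by default
     ("traditional"); a multiplicative random-effects SE is behind a flag.
   * **Weighted median (WM)** — the ordered ratios interpolated at
     cumulative normalized weight 1/2 (`p_j = (S_j - w_j/2)/S_tot`);
     consistent while valid instruments hold a majority of the weight.
   * **Penalized weighted median (PWM)** — weights multiplied by
     `min(1, 20 p_j)` where `p_j` is the chi-square(1) upper tail of the
     instrument's contribution `q_j = w_j (b_j - IVW)²` to Cochran's Q;
     this down-weights outlying, heterogeneous instruments.
   * **MR-Egger** — weighted regression of `Gamma` on `gamma` with a free
     intercept (weights `1/se_Gamma²`); the intercept estimates directional
     pleiotropy, the slope is the pleiotropy-adjusted effect.
   * **Cochran's Q** — `sum(w_j (b_j - IVW)²)` on J−1 df, a heterogeneity
     (hence pleiotropy) diagnostic.

   Results are reported as hazard ratios `exp(estimate)` with 95% CI
   `exp(estimate ± 1.96 SE)`.

4. **Genetic score and MR G×E** (`build_genetic_score`, `rescale_gs`,
   `stratum_associations`, `gxe_estimate`). The weighted score
   `GS_i = sum_j gamma_j g_ij` uses only continuous-scale instruments
   (binary-log-odds weights are not on the exposure unit). It is rescaled
   to the exposure unit by OLS of log CRP on GS among unaffected women,
   `beta0 + beta1·GS`; rescaling is affine, so the two scores are
   perfectly correlated (r = 1). The gene–environment-interaction
   estimator regresses per-stratum score–outcome log hazard ratios
   `Gamma_s` on per-stratum score–exposure slopes `gamma_s` across
   environment strata (weights `1/se²`, known-variance SEs). If pleiotropy
   is constant across strata while instrument strength varies, the slope
   is the pleiotropy-corrected causal effect and the intercept estimates
   the constant pleiotropy. The cited identification strategy is published
   without equations; this across-strata regression is its core identity
   and is what we implement. With exactly two strata it reduces to the
   two-point closed form. Equal `gamma_s` across strata leaves the slope
   unidentified, and the function refuses rather than extrapolate.

5. **Stratified and subtype pipelines** (`default_strata`,
   `run_stratified_mr`, `subtype_analysis`, `bh_adjust`). Modifier
   cutoffs: BMI >= 30 kg/m², WHR > 0.85, MET >= 10 h/wk, SFA >= 9% kcal,
   CES-D >= 0.06, >= 15 cigarettes/day, alcohol >= 14 g/day (one drink),
   family history yes/no, E-only and E+P durations in 5-year bins from
   non-use to >= 15 years, OC split at the 5-year median. Duration bins
   are half-open `[a, b)` (the closed/open sides are not printed in the
   source material; we fix this convention), with 0 years its own
   "non-use" category. Subtype analyses are cause-specific: events of
   other subtypes are censored at diagnosis. Strata with fewer than 10
   events (configurable) are reported as skipped, not estimated.
   Benjamini–Hochberg correction is applied within each analysis family
   (e.g. all strata of one modifier), via `stats::p.adjust`.

## Instrument strength

`f_statistic(r2, n, k)` exposes the standard approximation
`F = (r2/(1-r2)) · (n-k-1)/k`. Note that at R² = 0.06, n = 10,179 this
formula gives F ≈ 11 for k = 61 instruments and F ≈ 108.2 for k = 6; a
published value of 108.15 therefore corresponds to a handful of score-level
predictors rather than 61 separate instruments. The function computes the
formula; it does not attempt to reverse-engineer any particular printed
value.

## The synthetic cohort: what it emulates, and what it does not

All individual-level stages are exercised on cohorts from
`simulate_cohort()`, because the motivating data (a postmenopausal
multi-sub-study GWAS cohort) are access-restricted. The generator's
defaults *are* the study conditions:

* n = 10,179 women in 5 sub-studies; 61 independent variants (5 labelled
  binary-scale, 56 continuous) with effect-allele frequencies in
  (0.05, 0.5), effects scaled so the instruments jointly explain exactly
  6% of log-CRP variance in expectation;
* log CRP = centred additive genetic value + Gaussian noise, marginal
  SD 1 and mean 0.574, giving ~30% prevalence of CRP > 3 mg/L (the
  source material prints neither CRP's marginal distribution nor covariate
  means; these defaults are declared, not inferred);
* exponential baseline hazard 0.0031/person-year with true
  `theta = 0.2`, administrative censoring Uniform(16, 21) years
  (staggered enrolment over 5 years before a common study end) and
  exponential loss-to-follow-up solved from an administrative-censoring
  share of 0.786. The hazard and loss parameters were calibrated once, by
  Monte Carlo, to the printed cohort descriptors — ~5% cumulative
  incidence and ~16-year mean follow-up — and then frozen;
* lifestyle covariates drawn from documented marginals (age ~ U(50, 79)
  per the cohort's eligibility window; BMI log-normal with mean 28;
  hormone-use durations zero-inflated exponential; CES-D ~ Beta with mean
  0.062; and so on — see `simulate_phenotypes()`), all independent of
  genotype, so stage-2 covariates are pure noise by construction;
* ER/PR and HER2 labels drawn for events only (P(ER/PR+) = 0.75,
  P(HER2+) = 0.2), independent of CRP unless a subtype-specific `theta`
  is configured; effect modification enters as configured multiplicative
  shifts of `theta` within bins of a covariate;
* the two-sample generator `simulate_summary_stats()` draws
  `gamma_hat ~ N(beta_j, se)` and
  `Gamma_hat ~ N(theta·beta_j + shift·invalid_j, se)` with the invalid set
  chosen to carry a requested share of total inverse-variance weight; its
  effective sample sizes (exposure GWAS n = 200,000, outcome 50,000
  effective events) are the testbed scale at which bias and coverage of
  the estimators are measurable with a few hundred replicates.

What the generator does **not** emulate: realistic LD maps (an optional
Gaussian-copula block generator exists solely to exercise pruning),
genotype imputation, population structure beyond the supplied PC columns,
or dependence between lifestyle and genotype. Passing tests therefore
demonstrate the statistical machinery under the assumed model — they do
not validate the biological conclusions on real data.

## Numerical choices and edge cases

* Wald-ratio SEs are first-order (`se_Gamma/|gamma|`) by default, as is
  common for these estimators; second-order SEs, with an optional
  exposure–outcome covariance term for one-sample overlap, are available.
  The covariance default is 0 and we document this as a limitation rather
  than guessing an overlap correction.
* WM/PWM standard errors use a parametric bootstrap
  (`b* ~ N(b_hat_j, se_j)`, 1,000 draws, seeded). This scheme — the one the
  estimator literature itself uses — centres draws on the observed, noisy
  ratios and therefore overstates the median's sampling variability
  slightly: in our calibration simulations (1,000 replicates, 60 valid
  instruments) WM/PWM intervals cover the truth in ~96–97% of replicates
  at nominal 95%, while IVW is nominal (~94–95%). The intervals are
  mildly conservative, never anti-conservative; we keep the standard
  scheme rather than invent a different one.
* HWE is a plain 1-df Pearson chi-square on hard-call counts, no
  continuity correction. Monomorphic variants are in exact HWE (p = 1) but
  are excluded from pruning/score steps as zero-variance where relevant.
* Missing dosages in the score are mean-imputed at `2·eaf` with a logged
  count; Cox models are complete-case with dropped rows counted.
* Degenerate inputs fail loudly and early: empty instrument overlap, zero
  score variance among non-cases, zero events, identical stratum
  strengths, p-values outside [0, 1].
* Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; two runs with the same configuration and seed are
  byte-identical, including bootstrap SEs.

## Problem sizes used in the test suite

The suite keeps well under a desktop time budget by choosing the smallest
sizes at which each property is decisive: calibration checks use one
default cohort (n = 10,179); estimator bias/coverage use 500 two-sample
replicates (bootstrap 1,000 draws); the weighted-median breakdown sweep
uses 120 replicates at each of six invalid-weight fractions (0.20–0.80);
the one-sample recovery check uses 100 replicates of n = 10,000 cohorts
with 15 variants and `theta = 0.3`; PH-diagnostic size/power use 200
replicates. These sizes are the package's own choices; the corresponding
Monte-Carlo tolerances are stated next to each test.

## Known limitations

* The one-sample design reuses the same individuals for exposure and
  outcome; weak-instrument bias in one-sample MR is toward the
  confounded association, and the optional covariance term in the
  Wald-ratio SE is a placeholder for a full overlap correction.
* Cox models fit sub-studies separately and pool by fixed-effect
  meta-analysis; a stratified-baseline joint fit is a defensible
  alternative we did not implement.
* The G×E estimator assumes pleiotropy constant across strata; only the
  intercept itself speaks to that assumption.
* Subtype analyses treat competing subtypes by cause-specific censoring;
  subdistribution (Fine–Gray) models are out of scope.
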