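---
title: "Methods: likelihood-ratio risk models for first-trimester trisomy 21 screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-ratio risk models for first-trimester trisomy 21 screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t21screen)
```

## The screening model

First-trimester combined screening estimates each pregnancy's risk of
fetal trisomy 21 from maternal serum markers — PAPP-A (decreased in
affected pregnancies), free beta-hCG (increased), the lens-culinaris
weakly-binding alpha-fetoprotein variant AFP-L2 (increased) — and the
ultrasound nuchal translucency (NT) measurement, combined with the
maternal-age background risk. The calculation has three stages.

**MoM normalization.** Marker concentrations depend strongly on
gestational age and, for serum markers, on maternal weight (dilution).
Each concentration is therefore expressed as a multiple of the median
(MoM): the raw value divided by the population median, then divided by
the product of a gestational-age median curve
`10^(c0 + c1*GA + ... + c4*GA^4)` (GA in days) and a maternal-weight
correction `a - b/weight`. The package implements this product-form
adjustment exactly as published, with the conventional sequential
variant (raw over GA median, then weight correction) available through
`normalize_cohort(mode = "conventional")`. Only the AFP-L2 quartic
coefficient set is published; other markers default to the identity
median, and per-marker coefficients can be supplied via configuration.
Note two quirks of the published constants, reproduced deliberately:
the AFP-L2 quartic evaluates to ~0.05 (not ~1) at the cohort's median
GA of 89 days, and the weight correction is ~0.70 at the median weight
of 50.1 kg, so "adjusted MoM" values are on a shifted scale. Neither
affects discrimination — the Gaussian models are fitted to whatever
scale the adjustment produces — but absolute cutoff values are only
meaningful within one convention.

**Maternal-age prior.** The background risk is
`0.0000697 + exp(-18.4367 + 0.286*(age - 0.5))`, rising from about
1/14000 at age 20 to about 1/1200 at age 40. These constants differ
from other published age-risk regressions; they are kept verbatim as
immutable defaults of `age_risk_params()`, with all four parameters
configurable.

**Likelihood ratio and combined risk.** For a marker subset, affected
and control classes each get a multivariate Gaussian density fitted to
log10 adjusted MoM (mean vector, unbiased covariance). A subject's
likelihood ratio is the affected density over the control density at
their marker vector, computed via log-densities with a Cholesky
factorization and exponentiated last, so |log LR| up to ~700 cannot
overflow. The final risk is reported both ways: the traditional
"1 in N" denominator `N = 1/(LR * age risk)` and the ascending score
`risk_probability = LR * age risk` used for ROC analysis (the two
orderings are equivalent; ROC conventions need a score that rises with
risk). All 15 non-empty subsets of the four-marker panel are fitted by
`enumerate_models()` / `score_cohort()`.

The log10 transform is our choice: the source material never states
the modelling scale, but Gaussian modelling of log MoM is the standard
in prenatal screening and matches the multiplicative MoM scale.
`score_cohort(log_base10 = FALSE)` provides natural-scale modelling
for sensitivity analysis. Likewise, densities are fitted by
resubstitution (fit and evaluate on the same cohort) because that is
the design of the 40+40 study population being emulated; resubstitution
is optimistic by construction, and `cv_folds` enables stratified
cross-fitting when honest estimates are wanted.

## The synthetic cohort generator

No subject-level data are available for the study population this
package emulates — only group sizes (40 affected, 40 control) and
per-variable summaries: median and 2.5th/97.5th percentiles. The
generator treats those summaries as the study conditions.

Each marker's MoM distribution is a **two-piece (split) log-normal**:
on the log scale, `mu + sigma(z) * z` with `z` standard normal,
`sigma(z) = sigma_lower` below the median and `sigma_upper` above.
The three parameters are identified exactly by the three printed
numbers (each outer percentile maps to its own sigma through
`qnorm(0.975) = 1.959964`, kept as a documented constant at the
printed precision). The split family was chosen because the printed
intervals are visibly asymmetric on the log scale — e.g. control
PAPP-A 0.88 (0.20–3.74) — which a single log-normal cannot honour; a
pooled-sigma log-normal remains available (`pooled = TRUE`) for
sensitivity analysis. Demographics (age, weight, GA) use the same
construction on the natural scale, since their intervals are nearly
symmetric, and are clamped to plausibility bounds (age 15–50 y, weight
30–150 kg, GA 77–97 d) with a message when clamping occurs; the
affected group's long lower GA tail (2.5th percentile 69.1 d) makes
clamping routine there.

Markers are coupled by a **Gaussian copula**: correlated standard
normals mapped through each margin's quantile transform. The default
correlation is the identity because no inter-marker correlations are
published for this population; this is the single largest gap between
the synthetic conditions and real cohorts (real PAPP-A/free beta-hCG
correlations are material), and it is why multi-marker AUCs from
synthetic cohorts should be read as properties of the machinery, not
predictions for real data. The copula correlation is configurable; a
requested correlation rho implies a Spearman rank correlation of
`6/pi * asin(rho/2)` on the simulated MoM values, which the tests
verify.

Passing tests on these cohorts therefore demonstrates: calibration
(the generator reproduces the summaries it was given), correctness of
the scoring and evaluation machinery against independent oracles, and
stochastic reproduction of the single-marker headline numbers
(AFP-L2 AUC near 0.797, NT near 0.826, AFP-L2 specificity near 0.695
at the 1.234 MoM cutoff). They do not demonstrate performance on real
cohorts, where marker correlations, measurement error and exclusion
criteria (twins, IVF, smoking, diabetes) all intervene.

## Evaluation battery

* **Group comparison** (`compare_groups`): medians with 2.5th–97.5th
  percentiles per group and a Mann–Whitney U test with midranks, tie
  correction and 0.5 continuity correction — the Z statistic reported
  alongside p, matching screening-study tables.
* **ROC/AUC** (`roc`): AUC is the rank (concordance) statistic with
  half credit for ties, identical to the trapezoidal area under the
  stored curve. The 95% CI and the p-value against AUC = 0.5 use a
  seeded stratified bootstrap (default B = 2000); the Hanley–McNeil
  asymptotic variance is available via `ci_method = "asymptotic"`.
  The bootstrap was chosen as the default because the source material
  does not state its CI method and the bootstrap makes no binormal
  assumption at n = 40 per group.
* **Youden cutoff** (`youden_optimal`): maximizes sensitivity +
  specificity − 1; exact ties resolve to the higher-specificity
  threshold. A subject scoring exactly at the cutoff is screen-positive.
* **Diagnostic table** (`diagnostic_table`): DR, PPV, NPV, FPR, FNR,
  +LR, −LR from the 2×2 table at a cutoff. At FPR = 0 the +LR is
  undefined and reported as `NA` with a warning, mirroring the "-"
  convention in published tables. Prevalence is whatever the supplied
  cohort has (1:1 under the default design).
* **IDI / NRI** (`idi`, `nri`): IDI is the between-model change in
  mean risk separation of cases from controls, with the standard
  paired-difference normal test. NRI defaults to the continuous
  (category-free) form — P(up|case) − P(down|case) + P(down|control)
  − P(up|control) — because the published percentage improvements
  (2.78–25.72%) are inconsistent with a two-category NRI at any obvious
  risk threshold and no categories are named; categorical NRI with
  user thresholds is provided. Scores outside (0,1) are min-max
  rescaled per model pair, with a warning.
* **`evaluate_all`** assembles the three published table shapes: 15
  discrimination rows (Youden/sens/spec/cutoff, both as probability and
  "1 in N"/AUC/CI/p), 15 diagnostic rows at each model's Youden cutoff,
  and 7 improvement rows — every model lacking AFP-L2 against the same
  model with AFP-L2 added.

## Numerical choices and degenerate inputs

* Quartic GA medians are evaluated by Horner's scheme. At the
  published AFP-L2 coefficients the four non-constant terms at GA ≈ 89
  (≈ +720, −735, +331, −55) cancel to ≈ −1.29; a 50-digit-arithmetic
  golden value in the tests confirms double precision loses no
  accuracy that matters here.
* A class covariance with smallest eigenvalue ≤ 1e−12 gets a ridge of
  `1e-8 * trace/k` added to the diagonal (escalating if needed), always
  with a warning — degenerate fits are never repaired silently. A
  zero-trace (all-constant) sample falls back to an absolute 1e−8
  ridge.
* `maternal_age_risk` clips into (0, 1) with a warning; inputs outside
  the supported age (15–50 y) or GA (77–97 d) ranges warn but compute.
* The weight correction treats values ≤ 1e−12 as non-positive so the
  pole at `weight = b/a` is caught despite floating-point round-trip.
* All randomness flows from explicit seeds (`cohort_spec$seed`, the
  bootstrap `seed`), restored-RNG-state style, so cohort generation
  does not perturb the caller's RNG stream and staged pipeline runs
  compose byte-for-byte.

## Problem sizes used by the test suite

Calibration recovery uses 1e5 draws per distribution (3 Monte-Carlo-SE
bands); density-fit recovery uses 1e4 draws; median recovery at the
±5% band uses 8000 per group so that three sampling SEs of the widest
median (affected free beta-hCG) fit inside the band; the stochastic
AUC reproductions average 50 replicate 40+40 cohorts, the size the
emulated study used. These sizes were picked so every Monte-Carlo
check sits at least three SEs from its boundary under the default
conditions.

## Known limitations

* Independent markers by default: multi-marker results on synthetic
  cohorts understate (or overstate) nothing about real correlation
  structure because none is imposed.
* Resubstitution optimism: in-sample AUCs of the 15 models, especially
  the larger subsets at n = 40 per group, are upward-biased; the
  cross-fitting mode exists precisely to quantify that gap.
* The published product-form MoM adjustment and its constants are
  reproduced as printed even where they look like transcription
  artefacts (see the normalization section); users applying this
  package to real concentrations should supply their own laboratory's
  median equations.
* The measured power of the Mann–Whitney comparison between the
  calibrated AFP-L2 groups at n = 40 + 40 is ~0.88 at the 0.001 level,
  so a minority of replicate synthetic cohorts will not reach the
  strength of separation the emulated study observed.
```{r}
# the five-minute tour
cohort <- generate_cohort(default_cohort_spec())
scores <- score_cohort(cohort)
report <- evaluate_all(scores, cohort, boot = 500, seed = 1)
report
```
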