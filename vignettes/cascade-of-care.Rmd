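---
title: "Fixed-denominator cascades of care for T2D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-denominator cascades of care for T2D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecascade)
```

## The cascade model

A cascade of care summarises a chronic-disease care continuum as ordered
bars. For type 2 diabetes the package uses six: *prevalence*, *ever
tested*, *ever diagnosed*, *in care*, *in treatment*, *under control*.
Classification is per participant:

* **Case (prevalence bar).** FBG $\geq$ 126 mg/dL (capillary plasma) and
  HbA1c $\geq$ 6.5%, both non-missing — or self-reported use of T2D drugs
  or insulin, irrespective of biomarker values. The drug clause captures
  treated patients whose medication has brought biomarkers below the
  diagnostic thresholds.
* **Stages.** Nested conjunctions: tested = blood-glucose test within 3
  years; diagnosed = tested **and** ever told by a health worker; in care
  = diagnosed **and** care in the past 12 months; in treatment = in care
  **and** drugs/insulin in the past 2 weeks; under control = in treatment
  **and** HbA1c < 8%. Nesting is enforced by the engine: a respondent
  reporting a diagnosis but no test does not count as diagnosed. The raw
  (non-nested) flag counts are kept in the result for diagnostics.

All percentages — including *under control* — are taken against the fixed
denominator (the prevalence count), so consecutive drops read as
cumulative leakage rather than stage-conditional attrition. The advice
bundle (diet, weight, smoking, exercise — all four) is a secondary
indicator reported among the treated, not a bar.

Tunable parameters (`cascade_config()`): FBG case threshold (126 mg/dL),
HbA1c case threshold (6.5%), HbA1c control threshold (8%, must exceed the
case threshold), and the recall windows (3 years / 12 months / 2 weeks),
which document the self-report questions behind the flags. Missing
biomarkers fail the biomarker clause; no imputation is attempted, because
the analysis targets survey data where a missing capillary measurement
carries no usable signal.

## Wealth index

Household socioeconomic position is the first principal component of the
standardized 20-item asset-indicator matrix — the standard DHS
construction. Numerical choices: constant indicator columns are dropped
with a warning (they carry no variance and would make the correlation
matrix singular); the component is oriented so households owning more
assets score positive (sign fixed by the covariance between the score and
the standardized asset total); quintiles are assigned by score rank with
ties broken by household id, partitioning ranks $r = 1,\dots,n$ as
$q = \lfloor 5(r-1)/n \rfloor + 1$. Quintiles are computed
sample-relative (not against national cut-points, which are not
available for the study frame) and at household level, then joined to
participants. Ordinal indicators are treated as numeric after
standardization.

## Undiagnosed-status model

Among cases, *undiagnosed* means never told of the condition by a health
worker. The model is a maximum-likelihood logistic regression of
undiagnosed status on categorical covariate blocks (age group, sex,
marital status, education, wealth quintile, care-initiative setting), all
entered initially regardless of bivariate significance, followed by
backward elimination of **whole blocks**: at each step the block with the
largest block p-value is removed until every remaining block has
p < $\alpha$ (default .05). Block-level elimination is used because a
categorical variable is retained or dropped as a unit — per-level
elimination would leave uninterpretable partial blocks. Block p-values
are likelihood-ratio tests by default; Wald block chi-squares
($\hat\beta^\top V^{-1}\hat\beta$) are available. Ties in p are broken by
the documented covariate order. Reported effects are adjusted odds ratios
$e^{\hat\beta}$ with Wald 95% CIs $e^{\hat\beta \pm 1.96\,SE}$; reference
levels (age 60+, female, richest quintile, hospital-based setting) have
OR fixed at 1 with no CI.

Numerical choices: IRLS convergence tolerance $10^{-8}$ (up to 100
iterations; non-convergence is an error reporting the iteration count);
separation is detected as any non-intercept coefficient exceeding 12 in
absolute value — on the logit scale that is an odds ratio beyond
$e^{12}$, far outside anything estimable from survey data — and raises an
error naming the offending level(s). The check is applied to the final
model only: a quasi-separated level inside a block that backward
elimination removes anyway never surfaces in the reported table, and the
likelihood-ratio statistics used during elimination remain well defined
under separation.

The bivariate companion analysis cross-tabulates each covariate against
diagnosed/undiagnosed status and applies the Pearson chi-square test
without continuity correction, with a warning when any expected cell
count falls below 5 and Fisher's exact test behind a flag for such sparse
tables (e.g. the marital-status "never married" row).

## Synthetic survey generator

`generate_population()` emulates the study conditions of a five-setting
population survey of adults 40+: 1014 participants per care-initiative
setting (one participant per household), T2D prevalence 11.04%, and stage
retention equal to the observed cascade ratios (tested 353/560, diagnosed
given tested 309/353, in care given diagnosed 279/309, treated given care
273/279, controlled given treated 60/273). Its factorization is the
minimal structure the analysis stages need:

1. **Covariates first.** Age decays exponentially over 40–89 (mean ≈ 55);
   60% female; plausible education/marital mixes; household assets follow
   a one-factor model $P(\text{own}_j) = \text{logit}^{-1}(\alpha_j +
   1.2z)$ with latent wealth $z \sim N(0,1)$ and item difficulties
   $\alpha_j$ spread over $[-2.2, 2.2]$, so the PCA index recovers wealth
   with realistic measurement noise.
2. **Case status** is Bernoulli(prevalence), independent of covariates.
3. **Diagnosis is the only covariate-dependent stage** (matching the
   analysis design): $P(\text{undiagnosed} \mid \text{case}) =
   \text{logit}^{-1}(\beta_0 + x^\top\delta)$ with planted log-odds
   offsets $\delta$ (age 40–49, male, poorest quintile, per-setting) and
   $\beta_0$ calibrated so that at $\delta = 0$ the marginal diagnosed
   proportion equals the product of the first two retention
   probabilities. Non-zero offsets shift the marginal, as planted effects
   should.
4. **The remaining chain is nested Markov**: diagnosed implies tested;
   undiagnosed cases are tested with the probability that restores the
   marginal tested proportion; care, treatment and control follow as
   Bernoulli retentions of the preceding stage.
5. **Biomarkers are consistent by construction**: cases draw FBG in
   130–280 and HbA1c in 6.6–13 (controlled cases 6.6–7.9, treated
   uncontrolled 8.2–13); non-cases draw HbA1c truncated below 6.5, so the
   biomarker case definition recovers exactly the simulated case set,
   while non-case FBG (normal around 98 mg/dL) can exceed 126 — giving a
   raised-FBG-only group like the one real surveys show. Biomarker
   missingness is generated only on request (default 0%).

What the generator does **not** emulate: survey design weights and
cluster sampling (households are labels only; the emulated analysis is
unweighted), covariate-dependent prevalence, care-seeking dynamics over
time, drug use outside the treated stage, and joint covariate structure
beyond the planted diagnosis effects. Passing parameter-recovery tests on
these data therefore shows the estimator chain is consistent under the
assumed factorization, not that it is robust to confounding structures
the generator never produces.

## Fixture reconstruction

`reconstruct_fixture()` inverts published aggregate counts into an
individual-level dataset, deterministically (no RNG, idempotent). Records
are laid out in a fixed stage order; each covariate's printed
diagnosed/undiagnosed margins are filled exactly along that order. Two
design details matter:

* **Strided fills.** Filling every covariate sequentially along the same
  participant order makes the covariates nearly collinear, which
  degenerates (quasi-separates) any joint model fitted to the
  reconstruction. Each covariate is therefore laid out along a
  stride-permuted order (stride coprime to the group size, a different
  small prime per covariate) — one-way margins are unchanged, joints are
  crossed. Only printed margins are guaranteed either way; higher-order
  joints are synthetic, so multivariable estimates from the fixture are
  plausibility anchors only.
* **Wealth by construction.** Intended quintiles get nested asset
  patterns (asset $j$ owned iff quintile $\geq t_j$, thresholds 2–5, five
  assets each), with group sizes matched to the rank-partition capacities
  of the sample size, so the PCA wealth index reproduces the printed
  quintile table exactly.

Biomarker values are synthetic representatives satisfying each record's
stage constraints (cases FBG 150 / HbA1c 9, controlled cases HbA1c 7.2,
raised-FBG non-cases FBG 140 / HbA1c 6.0, others 95 / 5.4). The fixture
contains no drug-using records with missing biomarkers: how such
participants entered the original prevalence definition is not stated in
the source material, and the reconstruction takes the conservative
reading that all counted cases had the data their bar definitions need.
Inconsistent specs (non-monotone bars, mismatched margins, provider or
advice counts exceeding their denominators) are rejected with the
violated constraint named.

## Testing strategy and problem sizes

Engine outputs are checked against independent brute-force oracles
(record-by-record loops, an eigendecomposition oracle for the wealth
scores, a label-permutation null for the chi-square statistic).
Stochastic properties use: 200 replicates of 5000 participants for
planted-effect recovery (a planted age-40–49 odds ratio of 3.2 whose Wald
CI should cover the truth in $\geq 90\%$ of replicates) and for null
block elimination (each block eliminated in about 95% of all-null
replicates); and 200 seeds of 100,000 participants for cascade
calibration (mean bar proportions within 3 Monte-Carlo standard errors of
the configured retention products). These sizes give Monte-Carlo standard
errors around 1.5% on coverage proportions and below 0.1% on calibration
means.

One caveat the suite makes explicit: for very small contingency tables
(3×2, total n ≤ 30) the asymptotic Pearson p-value and the exact
conditional permutation p differ by up to ~0.2 even with all expected
counts ≥ 5, because the permutation null is discrete with large atoms at
the observed statistic. That comparison documents the limit of the
asymptotic approximation at such sizes; for the study-scale tables (n =
560) the approximation is excellent.

## Known limitations

* Percentages are displayed rounded half-away-from-zero to one decimal;
  stored values are full precision.
* No survey weights or clustered standard errors; the emulated analysis
  is unweighted and treats participants as independent.
* Profile-likelihood CIs are not implemented (Wald only).
* The fixture's higher-order joint distributions are synthetic; only
  printed margins are guaranteed.
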