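---
title: "Lifestyle classes and the genetics of biological aging: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifestyle classes and the genetics of biological aging: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`twinaging` implements a four-stage analytic chain for twin cohorts with
repeated adolescent lifestyle measurements and adult epigenetic-aging
outcomes: (1) latent class analysis (LCA) of mixed ordinal and continuous
lifestyle indicators; (2) comparison of biological-aging outcomes across
classes with the Bolck–Croon–Hagenaars (BCH) three-step correction;
(3) univariate twin variance-component (biometric) models; and (4) a
decomposition of outcome variance into genetic and environmental parts
shared with, or unique to, the lifestyle classes. A genetically structured
synthetic-cohort generator provides ground truth for every estimator, since
individual-level data of this kind are access-restricted in practice.

## The measurement model

Individuals carry ten indicators: BMI at ages 12/14/17 (continuous,
kg/m²), leisure-time physical activity at 12 (3 ordered levels) and at
14/17 (4 levels), and smoking status and binge drinking at 14/17 (4 levels
each). The K-class model assumes local independence within class; the
observed-data log-likelihood is

$$\ell = \sum_i \log \sum_{k=1}^{K} \pi_k \prod_{j \in \mathrm{obs}(i)} f_{jk}(y_{ij}),$$

with class-specific unconstrained category probabilities for ordinal
indicators (the exact-likelihood equivalent of free cumulative-logit
thresholds, avoiding a link choice) and class-specific means *and*
variances for BMI. Missing items simply drop out of the product — full
information maximum likelihood, unbiased under missingness at random
(MAR). Individuals missing all ten indicators are excluded.

Numerical choices:

* **EM with multistart.** Responsibilities are initialised from Dirichlet(1)
  draws; `n_starts = 50` by default, each burnt in for 40 iterations, the
  best 5 polished to convergence. Convergence is an absolute log-likelihood
  increment below `tol = 1e-6` (a relative criterion is far too loose at
  cohort-scale log-likelihoods, where it permits stopping thousands of
  likelihood points short of the optimum).
* **Variance floor.** Class-specific BMI variances are floored at
  `1e-4` times the marginal variance; floor hits are flagged, not fatal.
* **Label switching.** Classes are reported in canonical order: descending
  class proportion, ties broken by ascending mean of the last continuous
  indicator (BMI at 17 in the default battery).
* **Class-varying BMI variances** are the default (a literal reading of a
  threshold-and-moments measurement model); the within-class variance can
  be made class-invariant by passing suitably constrained starting
  configurations, but no switch is exposed — in our recovery experiments
  the class-varying form was never degenerate.

Class enumeration uses AIC, BIC and the sample-size-adjusted BIC
(`-2L + p log((n+2)/24)`), the average posterior probability of modal
assignment (AvePP) per class, and likelihood-ratio enumeration tests. For
the K vs K−1 comparison, the VLMR p-value refers `2(L_K − L_{K-1})` to a
chi-square with the parameter-count difference as degrees of freedom, and
the adjusted (LMR) variant scales the statistic by
`1/(1 + 1/(Δp·log n))`. The commercial implementation's weighted
chi-square internals are unpublished; this form reproduces its
characteristic behaviour — an adjusted p-value marginally above the
unadjusted one — and is deliberately conservative under the null, which we
verify by simulation. Twins enter the likelihood as individuals; the
non-independence of co-twins affects standard errors (handled by
family-clustered sandwiches downstream), not point estimates.

## BCH distal outcomes

Posteriors from the measurement model give the classification-error matrix
`D[k, s] = Σ_i p̂_ik 1(w_i = s) / Σ_i p̂_ik` (modal assignment `w`); each
individual receives the weight row of `H = D⁻¹` for their modal class.
Weight rows sum to 1 and may be negative — that is the mechanism by which
BCH removes the attenuation of classify-then-analyse. The distal model is
weighted least squares of the outcome on K class dummies (no global
intercept) plus shared covariates — female sex, within-sample standardized
age, raw pubertal development score (PDS), optionally adult BMI as a second
model. Standard errors are family-clustered sandwiches robust to the
negative weights; the equal-means test is a chi-square Wald test with K−1
degrees of freedom; pairwise contrasts carry 95% and 99% intervals and
standardized mean differences, where the SMD denominator is the
whole-sample SD of the outcome — the only convention that reproduces
published contrast/SD arithmetic of this design (e.g. 2.70/3.24 → 0.83).

## Twin biometric models

For MZ and DZ pairs, the ACE/ADE/AE/CE/E models maximise a two-group
exchangeable bivariate-normal likelihood with one grand mean, total
variance the sum of the components, and within-pair covariances
`a²+c²` (MZ) vs `a²/2+c²` (DZ), or `a²+d²` vs `a²/2+d²/4`. Incomplete
pairs contribute univariate marginals (FIML). Components are
unconstrained — negative estimates are legitimate sample outcomes and
clamping them would bias the downstream shared-variance differences.
Standardized shares get delta-method intervals from the observed
information.

Model fit is normal-theory ML chi-square against the exchangeable
saturated model (mean, variance, covariance free per zygosity group: six
moments, so e.g. the AE model has 3 df), CFI/TLI against an
independence baseline (common mean and variance, zero covariance), a
multigroup RMSEA, SRMR over standardized moment residuals, and BIC on the
number of individuals. Two deliberate simplifications: no
Satorra–Bentler scaling (the robust correction needs fourth-moment
machinery and changes p-values, not estimates), and the single-grand-mean
structure (outcomes enter as covariate-adjusted residuals with mean near
zero, so freeing four means would spend degrees of freedom on nothing);
software that frees per-member, per-group means will print larger df for
the same models. The DE model is excluded — dominance without additive
variance is biologically implausible. Opposite-sex DZ pairs are pooled
with same-sex DZ pairs; no sex-limitation models are fitted.

## Shared-variance decomposition

With class means `μ̂` from a covariate-free BCH model, residual scores are
`r_i = y_i − Σ_k w_ik μ̂_k` (BCH weight rows by default; posterior rows via
`weight_type = "posterior"`). AE models are fitted to the outcome and to
the residuals, and the shared proportions are

$$\mathrm{shared_A} = \frac{a^2_{tot} - a^2_{res}}{Var_{tot}}, \qquad
\mathrm{shared_E} = \frac{e^2_{tot} - e^2_{res}}{Var_{tot}},$$

with `Var_tot` the total-fit model-implied variance, so that shared plus
unique proportions sum to one *exactly* and `Var(model)` is derived as
`Var_tot − Var_res`. Negative shared estimates (possible by sampling) are
reported with a warning; `clamp_zero = TRUE` reproduces presentation-style
stacked figures.

One property of this estimator deserves emphasis: classification noise in
the residual scores is independent across individuals given the true
classes, so it inflates the residual *nonshared environmental* component
but leaves within-pair covariances — and hence the residual genetic
component — clean. The shared-genetic proportion is therefore estimated
essentially without attenuation even at modest entropy (~0.8), while the
shared-environment proportion is biased toward zero at low entropy. Our
end-to-end recovery tests accordingly assert unbiasedness for the
shared-genetic proportion only; conclusions about shared environmental
variance from this design should be treated as lower bounds. One
degenerate corner is also worth knowing about: when the classes do not
differ in the outcome at all, the estimated class means fit pure noise and
the shared-genetic estimate acquires a small positive bias of order
`1/n_pairs` (about +0.002 at 365 pairs). The meaningful null — a real
class structure whose membership is environmentally determined — is
estimated without detectable bias.

## The synthetic cohort

`generate_cohort()` draws twin families (MZ / same-sex DZ / opposite-sex
DZ at 34/33/33% by default). Class membership is the ordered-threshold
discretisation of a standard-normal liability `L = √h²·G + √(1−h²)·U`,
where `G` is shared completely within MZ pairs and correlated 0.5 within
DZ pairs; thresholds are placed to give the configured class proportions
(default 32.0/19.9/22.8/9.5/15.9% for the healthiest, low-normal-BMI,
high-normal-BMI, high-BMI and unhealthiest patterns). The probit-style
threshold mechanism makes `h²` directly interpretable and the MZ/DZ
concordances analytic. A small centred sex shift (default ±0.075 SD)
reproduces the mild male excess in the healthier/heavier classes without
moving the marginal class proportions. `h² = 0.7` reflects the
substantial heritability that behaviour-pattern liabilities show in twin
cohorts of this age; it is a generator convention, not an estimate.

Indicators are drawn independently given class. Ordinal profiles follow
the default class-conditional probability tables; BMI is normal within
class with class-specific SDs following a constant coefficient of
variation (dispersion grows with the level, as BMI does empirically),
calibrated so the mixture reproduces the overall SDs of 2.6/2.7/3.0 at
the three ages given the class means and proportions. Outcomes are

`y = μ_class + covariate effects + resid_sd · (√(f·a²)·G + √((1−f)·a²)·G_u + √(e²)·ε)`,

with `a² + e² = 1` as residual shares, `G_u` a second twin-structured
genetic score, and `f = shared_a_frac` the fraction of outcome genetic
variance carried by the class-liability genetic score. Default outcome
settings use AE shares of 0.65/0.73/0.62/0.68 for PhenoAge and GrimAge
acceleration and the two pace-of-aging measures, class means equal to
published covariate-adjusted contrasts, residual SDs derived from the
overall outcome SDs net of between-class variance, and `f` calibrated a
priori from the generator's covariance algebra so the implied
shared-genetic proportions sit near the published decomposition. Item
missingness is Bernoulli with a logit in fully observed sex and age only
(MAR by construction), at marginal rates rising from ~2–4% at age 12 to
~18% at 17; outcomes are observed for a ~18% subsample of pairs, most of
them complete, emulating a biological substudy of roughly 800 individuals
with ~365 complete pairs.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: within-person tracking of BMI and behaviour
across ages beyond what class membership induces (local independence is
exact in the generator), non-normal within-class BMI, measurement error in
self-reports, and zygosity-dependent outcome ascertainment. The
local-independence point has one visible consequence: fitted classification
quality is modestly lower in synthetic cohorts (minimum AvePP ≈ 0.72–0.75)
than the ≈ 0.78 reported for comparable real data, where within-person
tracking sharpens the posteriors of a model that assumes independence.
We treat that gap as information about the generator, not a reason to move
its parameters: tightening within-class SDs to force AvePP up would break
the printed marginal SDs the generator is calibrated to.

`true_shared_proportions()` is the generator's oracle: it simulates ≥10⁶
latent individuals, computes class-conditional outcome means (which
include the class-linked part of the shared genetic score — the class
structure "explains" that part by construction), and projects the pooled
pair moments of the outcome and of the true-class residuals onto the AE
structure by minimising the population ML discrepancy. This projection is
implemented independently of the package's likelihood code so recovery
tests compare two separate routes to the same quantity.

## Problem sizes and defaults in the test suite

The suite exercises the estimators at the scale a desk replication
affords: one full-size cohort (2557 pairs, 5114 individuals) and 20
replicates for class-recovery checks; 500 replicates of 154 MZ + 211 DZ
pairs for the AE model; 200 pipeline replicates per setting (365 pairs,
classification entropy ≈ 0.76) for end-to-end recovery of the
shared-genetic proportion at generating values near 0, 0.05 and 0.13; and
500 replicates for the null calibration of the BCH Wald test. Enumeration
null simulations cap EM iterations; near the null the likelihood surface
is flat and any shortfall only makes the tests more conservative, which is
the direction being verified.

## Known limitations

* The enumeration tests approximate an unpublished reference
  distribution; p-values near a decision boundary should be read with the
  simulation evidence (conservative under the null) in mind.
* Chi-square p-values for the biometric models are normal-theory, not
  robust (no Satorra–Bentler scaling).
* The ICC confidence intervals use a Fisher-z approximation on the
  double-entry correlation and are not corrected for twin-of-twin nesting
  across measures.
* The residual-score step uses plug-in expectations, not shrinkage factor
  scores; the shared-environment proportion is attenuated at low entropy
  (see above).
* Whether covariate-free class means or posterior-row weighting better
  mirrors any particular published workflow is not always documented
  there; both weightings are available (`weight_type`), as are modal
  (default) and proportional assignment for the classification-error
  matrix.
* Age acceleration is residualised within the analysis sample
  (`age_acceleration()`); clock calculators that residualise against an
  external reference regression will differ by an affine transformation,
  which the class contrasts and variance shares are insensitive to.
* The sample-size-adjusted BIC uses the number of individuals contributing
  to the likelihood, ignoring the twin clustering; this matches the
  point-estimate convention of treating individuals as the likelihood
  unit.
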