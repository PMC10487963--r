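---
title: "Reference centiles, aging types and equivalent years of life for an immune age index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference centiles, aging types and equivalent years of life for an immune age index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoclock)
```

## The problem

Immunosenescence — the age-related remodelling of the immune system — does
not run in lockstep with chronological age. The immune age index IMMAX
summarizes five flow-cytometry blood-cell frequency ratios (NK:T,
CD4:CD8, memory:naive CD4, memory:naive CD8, and the CD28neg fraction of
CD8 T cells) into a single score on the unit interval that rises with age.
On its own, an IMMAX value is hard to interpret: a value of 0.5 is
unremarkable at 75 but high at 30. The remedy, borrowed from pediatric
growth charts, is a set of *age-conditional reference centiles*: percentile
curves P03, P15, P50, P85 and P97 of IMMAX as functions of age (spaced
roughly one standard deviation apart under a Gaussian), against which an
individual is located.

Everything downstream follows from those curves:

* **Aging types.** The five curves partition the IMMAX scale at every age
  into six ordered categories, from 1 (below P03, slowest immunological
  aging) to 6 (at or above P97, fastest). Boundary values belong to the
  upper category, so the partition is exhaustive and deterministic, and a
  subject exactly on the median is rated 4.
* **Individual centiles.** The distributional model also yields
  `F(IMMAX | age)`, a subject's exact position in its age-matched reference
  population. By construction these centiles are uncorrelated with age.
* **Equivalent years of life (EYOL).** Inverting a monotone reference curve
  (usually P50) maps an IMMAX value to the age at which the reference
  attains it; EYOL minus chronological age is the *immunological age gap*,
  positive for accelerated and negative for decelerated immune aging.
* **Longitudinal change.** For baseline/follow-up pairs, the changes in
  EYOL and age gap are algebraically linked through the follow-up period
  length (FPL): `delta EYOL = delta age gap + FPL`.

## Three centile estimation algorithms

The package fits the percentile curves in three ways, mirroring the common
methodological choices for reference intervals, so that downstream ratings
can be compared across algorithms:

**LMS-type location-scale-shape model (`fit_lms`).** IMMAX is mapped to the
real line by the logit (clipping at `1e-4`), and the transformed index is
modelled as a sinh-arcsinh (shash) distribution whose location, log-scale
and skewness are penalized-spline functions of age, with a constant
tail-weight, estimated by penalized maximum likelihood (REML smoothness
selection) via `mgcv::gam`. This is the package's realization of the
location/scale/shape ("GAMLSS"/LMS) centile tradition. The classical
Box-Cox Cole-Green construction requires a positive response and is
therefore ill-posed on the signed logit scale; the sinh-arcsinh family
plays the same role there — location, scale and a shape parameter that
skews the distribution — while remaining fully distributional, so
individual centiles, arbitrary percentiles and probability integral
transform (PIT) diagnostics are all available in closed form. One
technical footnote: the scale link of `mgcv`'s shash family carries an
additive floor `b` (default 0.01) that the family's quantile and CDF
helpers ignore; the package constructs the family with `b = 1e-6` so the
fitted link and the quantile/CDF inversions agree to numerical precision.
Fitted parameter curves are tabulated on a 0.1-year grid; outside the
observed age range they are frozen at their boundary values.

**Linear quantile regression (`fit_lqr`).** For each tau, the line
minimizing the pinball (check) loss. The solver is exact: an asymmetric
iteratively-reweighted least-squares pass gives a warm start, and the fit
is then polished by enumerating candidate lines through pairs of
low-residual observations — the optimal quantile line interpolates at
least two data points, so this terminates in a basic solution. The test
suite verifies exact agreement with an exhaustive all-pairs oracle on
small datasets. LQR curves extrapolate linearly to any age.

**Penalized-spline quantile regression (`fit_nqr`).** For each tau, a
cubic B-spline on equally spaced knots (default 10 coefficients)
minimizing pinball loss plus a squared second-difference penalty on the
coefficients (a quantile P-spline). The penalty defaults to the minimizer
of a Schwarz-type criterion, `log(mean pinball) + log(n)/(2n) * edf`, over
a log-spaced grid; as the penalty grows the curve collapses onto the LQR
line. The spline basis does not exist outside the observed age range, so
NQR curves refuse to extrapolate and cannot back a reference curve.

Raw curves from any algorithm may cross in finite samples; predictions are
therefore monotonically rearranged (sorted across taus at every age)
before use. Rearrangement preserves each marginal fit and is simpler than
constrained estimation; the limitation is that the post-hoc curves are no
longer the exact per-tau optimizers where crossings occurred.

## Agreement between rating algorithms

Ratings of the same cohort by different algorithms are compared with
confusion matrices, Spearman correlation, and Krippendorff's alpha,
`alpha = 1 - D_o / D_e`, computed from the coincidence matrix of pairable
within-unit values. The default difference function is ordinal (the six
aging types are ordered), weighting a disagreement between categories by
the squared marginal mass lying between them; a nominal metric is
available. `alpha = 1` is perfect agreement, `alpha = 0` chance-level; an
all-identical rating matrix has `D_e = 0` and raises an undefined-agreement
error rather than returning 1. Confidence intervals use a percentile
bootstrap over units (default `B = 1000`), with degenerate resamples
skipped and counted.

## Reference curves, EYOL and the age gap

`build_reference` evaluates a model's P50 (or the hypothetical composite
below) on a 0.1-year grid over ages 18 to 100, enforces monotonicity by
pool-adjacent-violators isotonic regression, and records extrapolation
slopes from the outer five grid-years. `eyol` inverts the curve by linear
interpolation; flat segments return the midpoint of the matching age
interval; IMMAX values outside the curve's range extrapolate linearly and
may map to ages above 100 or below 18 — even negative — which is the
expected behaviour when a bounded index is referred to a curve covering
only the adult range.

The *hypothetical reference* (HYP) addresses exactly that: instead of a
fixed centile it follows a percentile profile rising linearly from the
0.5th percentile at age 19 to the 99.5th at age 99 (1.2375 ~ 1.24% per
year), held at those percentiles over [18, 19) and (99, 100], with IMMAX 0
pinned to age 18 and IMMAX 1 to age 100. Built on the distributional
model's quantiles, it maps the whole unit interval into the adult age
range — at the price of inducing a negative correlation between the
resulting age gap and chronological age, which the test suite checks as a
sign property.

## The synthetic cohort generator

No real cohort ships with the package; a seeded generator provides data
with the statistical structure the analysis assumes, plus the true
conditional quantile function as an oracle for parameter recovery:

* **Ages** from a mixture of uniform components, by default
  (18-40, weight 0.45), (40-65, 0.35), (65-97, 0.20) — a pooled adult
  cohort with full coverage of the range and a thinning tail at old age.
* **IMMAX** as `plogis(mu(age) + sigma(age) * z(u))` with `mu`, `sigma`
  linear in age, `u` the subject's latent centile, and `z` a
  median-centred sinh-arcsinh standard quantile (default skewness 0.25,
  mildly right-tailed). Using sinh-arcsinh rather than a skew-normal gives
  closed-form quantiles *and* CDF and makes the LMS-type fit exactly well
  specified, so "well-specified simulation" is a precise statement in the
  tests. Defaults: `mu = -0.8 + 0.014 * age` (median IMMAX ~0.31 at 18,
  ~0.65 at 97), `sigma = 0.05 + 0.0007 * age` (spread roughly doubling
  over the range). These values keep the age-median near-linear on the raw
  IMMAX scale and the conditional spread moderate, which is what makes a
  median reference fitted on n = 500 invert follow-up changes into years
  with little bias or sampling noise; broader settings shift mean
  delta-EYOL visibly below the follow-up period through inverse-logit
  compression.
* **Biomarkers** as monotone transforms (exp, inverse-logit) of
  `loading * logit(IMMAX) + noise`, all five loadings positive, noise
  scales chosen so that a one-component principal-component regression
  recovers the latent index with Pearson R ~ 0.93 at n = 1000. The
  memory:naive CD8 ratio carries the strongest loading; the first
  principal axis is sign-aligned to it.
* **Follow-ups** advance age by the FPL and perturb the latent centile on
  the probit scale (default SD 0.15, clamped to (0.001, 0.999)); zero
  drift preserves each subject's centile exactly, isolating movement along
  the reference curves.
* **Age-stratified subsampling** uses half-open 10-year bins and
  largest-remainder rounding, so subsample and remainder always partition
  the cohort.

What the generator does *not* emulate: the real joint distribution of the
five biomarkers (loadings and noise scales are structural placeholders),
sex differences (sex is a random label), assay batch effects, and any
cohort heterogeneity beyond the age mixture. Passing tests demonstrate
that the algorithms recover known structure and that the pipeline's
invariants hold — not that the defaults reproduce any real population's
parameters.

## Numerical choices

* LQR polish pool: the 40 smallest absolute residuals, up to 5 rounds;
  IRLS floor `1e-7`, convergence `1e-11`.
* NQR IRLS: floor `1e-6`, up to 60 iterations; penalty grid `10^-2` to
  `10^5` (8 points).
* LMS smooth bases: k = 10 (location), 10 (log-scale), 5 (skewness);
  non-convergence of the outer REML iteration is an error carrying the
  iteration count and gradient, not a silent result.
* Centile-model predictions clip to [0, 1] after rearrangement; the
  reference-curve grid step of 0.1 years supports the documented 0.05-year
  round-trip accuracy (one half grid step) for strictly increasing curves.
* `delta age gap` is computed as `delta EYOL - FPL`, which is the same
  quantity as the difference of per-visit gaps but keeps the linkage
  identity exact in floating point.
* Wilcoxon tests: exact for 25 or fewer non-zero differences, continuity
  corrected normal approximation otherwise; zero differences dropped; an
  all-zero delta column is reported as degenerate. The cross-reference
  delta-EYOL family is Holm-adjusted by default (configurable).

## Problem sizes used in the checks

The bundled checks run at sizes chosen to make the statistical properties
sharp while staying quick on a single CPU: centile fits and agreement on
one cohort of n = 1600; PCR recovery at n = 1000; longitudinal calibration
on n = 500 baseline/follow-up pairs; solver-vs-oracle enumeration at
n <= 7 where exhaustive search is exact. The acceptance script
(`scripts/acceptance.R`) regenerates everything from scratch under a
caller-supplied seed.

## Known limitations

* Rearrangement repairs crossing curves but does not prevent them; heavily
  undersmoothed NQR fits can still wiggle between the evaluation grid.
* Beyond the observed age range the LMS parameter curves are frozen, so
  individual centiles of follow-up visits past the oldest fitted age are
  mildly biased; the effect is negligible for the default cohorts (about
  3% of subjects, bias well under a centile point on average).
* The delta-centile versus delta-age-gap correlation is high (about 0.9 to
  0.95) but not perfect: the centile-to-IMMAX Jacobian varies with age,
  and along-curve aging contributes a drift-independent component to the
  gap change. The corresponding *cross-sectional* correlation between
  centiles and age gaps exceeds 0.95.
* Krippendorff's alpha is the only agreement coefficient provided; there
  is no per-rater bias modelling.

## A worked run

```{r example, eval = FALSE}
params <- generator_params(seed = 42)
cohort <- generate_cohort(1600, params)

lms <- fit_lms(cohort$age_years, cohort$immax)
lqr <- fit_lqr(cohort$age_years, cohort$immax)
nqr <- fit_nqr(cohort$age_years, cohort$immax)

ratings <- cbind(
  LMS = rate_aging_type(lms, cohort$age_years, cohort$immax),
  LQR = rate_aging_type(lqr, cohort$age_years, cohort$immax),
  NQR = rate_aging_type(nqr, cohort$age_years, cohort$immax))
krippendorff_alpha(ratings[, c("LMS", "LQR")])

ref <- build_reference(lms, "P50")
gap <- age_gap(ref, cohort$immax, cohort$age_years)

baseline <- generate_cohort(500, generator_params(seed = 7, centile_drift_sd = 0))
followup <- generate_followup(baseline, fpl = 5,
                              generator_params(seed = 7, centile_drift_sd = 0))
deltas <- change_from_baseline(rbind(baseline, followup), lms,
                               list(LMS_P50 = ref))
longitudinal_report(deltas)
```
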