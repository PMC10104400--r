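---
title: "Twin variance-component models for actigraphy sleep phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin variance-component models for actigraphy sleep phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsleep)
```

`twinsleep` estimates how much of the individual variation in adolescent
sleep-wake behaviors — sleep onset, wake time, sleep duration, sleep
midpoint, and diary-reported restorative sleep — is attributable to
additive genetics (A), shared family environment (C), and unique
environment including measurement error (E). This vignette documents the
models, the synthetic-data generator that stands in for raw cohort data,
the numerical choices, and the package's known limitations.

## The classical twin design

Monozygotic (MZ) co-twins share essentially all segregating alleles;
dizygotic (DZ) co-twins share half on average. Both kinds of pair share a
household. If a standardized phenotype decomposes as
$y = a\,A + c\,C + e\,E$ with independent standard-normal latent factors,
the within-pair covariance is $a^2 + c^2$ for MZ pairs and
$\tfrac12 a^2 + c^2$ for DZ pairs: the additive-genetic correlation is
fixed at 1.0 (MZ) and 0.5 (DZ) by kinship, the shared-environment
correlation at 1.0 for both, and the unique-environment correlation at 0.
An excess of MZ over DZ similarity is therefore evidence of genetic
influence. Dominance (non-additive) models are out of scope: C and D
cannot be estimated jointly from twins reared together, and the twin
correlations this design targets (DZ more than half of MZ) support ACE.

`fit_ace_family()` maximizes the resulting two-group bivariate-normal
likelihood. Paths $a, c, e$ are estimated as unconstrained coefficients
and squared, so variance components are nonnegative by construction and
the likelihood is invariant to sign flips; the grand mean is a single free
parameter because the models run on age- and sex-residualized z-scores.
Unpaired twins ("singletons") enter through the marginal likelihood of the
observed member, the full-information treatment under missing-at-random.
Sub-models AE, CE and E fix the corresponding paths at zero; E has a
closed-form solution. `fit_saturated()` estimates per-zygosity means,
variances and the ML twin correlation freely, with optional equality
constraints across twin order and zygosity, each tested against the free
model by likelihood ratio — the standard preliminary check before
structural modeling.

Model choice uses Akaike's information criterion computed as
$\mathrm{AIC} = -2\ln L + 2k$ with $k$ the number of free parameters;
only AIC differences within one data set are meaningful, so the additive
convention is immaterial. `compare_models()` ranks fits (ties broken by
fewer parameters) and reports likelihood-ratio p-values against the ACE
fit.

The closed-form decomposition from a twin-correlation pair,
$a^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = 2 r_{DZ} - r_{MZ}$,
$e^2 = 1 - r_{MZ}$ (`falconer()`), is just-identified when the model is
fitted to a correlation pair alone. The test suite exploits this as an
oracle: on data whose sample moments are set exactly to a population ACE
structure, the ML fit must reproduce `falconer()` to near machine
precision, which pins down the likelihood code independently of the
optimizer path.

### Confidence intervals

`profile_ci()` inverts the profile likelihood: the 95% interval for a
standardized component is the set of values whose profile $-2\ln L$
(re-maximizing the mean, the total variance, and the remaining free
proportion) rises at most $\chi^2_{1,0.95} = 3.84$ above the minimum,
clipped to $[0, 1]$. Profile intervals respect the boundary at zero,
where Wald intervals fail for variance components. Coverage is verified
by simulation in the test suite (500 replicates at 200 + 200 pairs).

## Bivariate decompositions

For two phenotypes the per-pair observation is the 4-vector
$(x_1, y_1, x_2, y_2)$. Each source contributes a $2\times2$ covariance
matrix; cross-twin blocks are $A + C$ (MZ) or $\tfrac12 A + C$ (DZ).

* **Cholesky decomposition** (`fit_cholesky()`): $A = L_A L_A^\top$ etc.
  with lower-triangular $L$. This saturates the two-trait covariance
  structure, so the attained $-2\ln L$ is identical under either variable
  order — an invariance the tests check to $10^{-6}$. What depends on the
  order is the common/specific split of the *second* trait (its variance
  through the first trait's factor vs its own), which is why the model is
  conventionally run both ways; the package exposes `order = c(1, 2)` and
  `c(2, 1)`.
* **Constrained independent pathway** (`fit_independent_pathway()`): one
  common factor per source loading on both traits, plus trait-specific
  factors. With two traits a source whose two common loadings are free has
  four parameters against only three identified covariance entries — a
  flat ridge — so the package's default (and only identified) scheme
  equates the loadings within each source, giving 9 structural parameters
  against the 9 distinct moment conditions of a two-group bivariate twin
  design. Requesting free loadings raises an identification error before
  optimization. `drop =` fixes named paths at zero, the usual follow-up
  when estimates sit at the boundary; dropping a path whose estimate is
  zero leaves $-2\ln L$ unchanged, which the tests verify on
  moment-matched data. A consequence worth stating plainly: on
  standardized traits the equal-loadings scheme forces the common variance
  of a source to be equal for both traits, so unequal published common
  percentages for two z-scored traits cannot have come from this strict
  scheme — the package treats such splits as generator-side truths rather
  than fittable quantities, and recovers the full source covariance
  matrices (from which overlap percentages follow) via the Cholesky fit.

`correlation_decomposition()` turns fitted (or true) $A, C, E$ matrices
into the genetic correlation $r_G = A_{12}/\sqrt{A_{11}A_{22}}$
(analogously $r_C$, $r_E$) and the phenotypic correlation
$r_P = \sum_s S_{12}/\sqrt{V_1 V_2}$, whose per-source contributions sum
to $r_P$ exactly. Because squared paths make the likelihood sign-blind,
reported loadings follow the convention of nonnegative diagonals /
first-trait loadings; the sign of $r_G$ between, say, duration and
midpoint therefore depends on the coding direction of the phenotypes, and
users flipping a trait's sign will see $r_G$ flip with it.
`shared_proportion(common, total)` reports `100 * common / total` rounded
to integer percent, matching the display convention of variance-overlap
figures.

## What the synthetic-data generator emulates

The generator's defaults encode the study conditions of a pooled
adolescent twin actigraphy protocol:

* **Cohort** (`simulate_cohort()`): 93 MZ and 117 DZ complete pairs plus
  75 unpaired twins; ages uniform on 9–17 shared within pair; 55% female,
  MZ co-twins same-sex, DZ co-twin sex independent (so opposite-sex DZ
  pairs occur). Singletons take the paired MZ:DZ ratio.
* **Familial structure** (`simulate_ace_pairs()`): per-family A drawn
  shared for MZ and as $\sqrt{0.5}\,\text{family} +
  \sqrt{0.5}\,\text{individual}$ for DZ, per-family C, per-person E —
  kinship correlations exact by construction, default components
  $a^2 = 0.62, c^2 = 0.08, e^2 = 0.30$ (a sleep-duration-like structure
  implying population twin correlations 0.70/0.39).
* **Nights** (`simulate_night_records()`): 14 nights per subject on a
  repeating 7-day calendar starting Monday; nights whose evening is
  Friday or Saturday, plus configurable holiday blocks, are nonschool
  (setting `holiday_nights = 1:14` reproduces subjects measured entirely
  during holidays). Per-phenotype school-night means follow descriptive
  values typical of this age group (onset 21:38, wake 06:39, duration
  7 h 35 m, restorative sleep 40% of nights), with nonschool shifts of
  +25, +15, +2 min and +6 points, age slopes of +14, +6, −7 min/year and
  −2 points/year centred at age 13, a −15 min male duration contrast, and
  nightly noise SDs of 45/40/50 min chosen as realistic within-subject
  night-to-night variability. Restorative sleep is a nightly Bernoulli
  whose subject-level logit carries the ACE latent (logit SD 1.5),
  keeping a continuous familial liability behind binary diary codes.
  Device data go missing at 8% per night; 1% of nights get device onsets
  displaced 6.2–9 h from the diary bedtime, the corruption the disparity
  filter must catch.
* **Raw angles** (`simulate_angle_series()`): 5 s arm-angle epochs over an
  evening-to-noon recording; epoch-to-epoch jitter below the 5° threshold
  during sleep, super-threshold movements at a configurable rate while
  awake, optional 1-minute arousal bursts, and a diary window extending
  beyond the true sleep window with configurable noise. True onset/wake
  are snapped to the epoch grid and returned so detector error can be
  scored against ground truth.

All clock arithmetic uses minutes since 12:00 noon of the night's evening,
because onset distributions straddle midnight and hours-since-midnight
arithmetic would order 01:11 before 21:51.

What the generator does *not* emulate: wear-time artifacts and device
calibration drift, non-Gaussian night-level noise, sex-limitation
(different genetic architectures by sex), age trends in the variance
components themselves, and correlated nightly noise across phenotypes
(each phenotype gets an independent familial latent, so cross-phenotype
bivariate structure comes only from the dedicated bivariate generator).
Passing tests therefore demonstrate that the estimators recover the
structure this generator encodes — unbiasedness at scale, oracle
equivalence, interval coverage — not that real adolescent data satisfy
bivariate normality or missing-at-random wear gaps.

## Preprocessing choices

* Nights with missing device data or with |device onset − diary bedtime|
  strictly greater than 6 h are dropped; a disparity of exactly 6 h is
  retained (the exclusive reading of an "extreme (±6 h)" rule discards
  fewer data). Subjects keeping fewer than 7 of the 14 nights are then
  dropped; because the night rules are per-night and the subject rule
  counts survivors, sequential application equals joint application and
  the filter is idempotent.
* z-scoring computes $(x - \bar x)/s$ over available subjects; values with
  |z| > 4.00 are removed first, survivors with |z| > 3.29 winsorized to
  the signed threshold, and z-scores are *not* recomputed after removal —
  a deterministic single pass. Re-standardizing cleaned scores would
  shrink the scale slightly; the clamp rule itself is idempotent.
* Residualization on age and sex is ordinary least squares, ignoring
  family clustering: clustering affects standard errors of the screen, not
  the residuals the twin models consume. It is run within each analysis
  sample (full, younger, older), so stratified analyses subset first.
* Subjects with no school nights (holiday-only participation) simply lack
  the school-night phenotype and re-enter bivariate school/nonschool
  models through the missingness-pattern likelihood.

## Numerical notes

Likelihoods are evaluated from per-group sufficient statistics (scatter
matrices per zygosity and missingness pattern), making each evaluation
O(1) in the number of families. Optimization is quasi-Newton (`nlminb`
then a BFGS polish) from a moment-based start (Falconer components for
univariate fits; kinship-weighted moment estimates projected to positive
definiteness for bivariate fits) plus a deterministic spread of four
rescaled restarts — deterministic so that a fit depends only on its data,
never on ambient RNG state. Convergence tolerances are set to $10^{-13}$
relative so that nested-model likelihood orderings and the two Cholesky
variable orders agree to $10^{-6}$. Degenerate inputs fail loudly:
zero-variance phenotypes, rank-deficient covariate designs, non-positive
implied covariances, under-identified constraint sets, and empty age
strata all raise classed errors.

Problem sizes used in the shipped checks were chosen to make Monte-Carlo
error small relative to the tolerance being asserted: 50,000 pairs per
zygosity for generator correlation limits (tolerance 0.01), 200,000 pairs
for the implied-covariance check, 200 replicates at 93 + 117 pairs for
small-sample recovery, 100 replicates of 400 subjects for the age-slope
recovery, and 500 replicates at 200 + 200 pairs for profile-interval
coverage.

One estimator property deserves flagging: at 93 + 117 pairs the mean ML
estimate of $a^2$ under an ACE truth of 0.62/0.08/0.30 sits a few
hundredths below 0.62. This is the boundary effect of nonnegative
variance components — in replicates where the sampled DZ correlation
exceeds half the MZ correlation by chance, $\hat c^2$ piles up at zero
and the refitted $\hat a^2$ is pulled toward the within-pair covariances
rather than the Falconer contrast — and it shrinks as the cohort grows.
The recovery checks assert the mean within the Monte-Carlo tolerance
appropriate to that sample size rather than exact unbiasedness.

## Limitations

Two zygosity groups only (no five-group sex-limitation models), no
dominance models, no longitudinal modeling of the age trends, no raw
30 Hz accelerometer ingestion or device calibration, and no
molecular-genetic functionality. The bivariate layer handles exactly two
traits; multivariate extensions (more traits, common-pathway models) are
out of scope. Reported integer percentages in decomposition tables are
rounded independently and need not sum to exactly 100.
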