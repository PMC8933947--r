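---
title: "Methods: comparing 10-year CVD risk models on a synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing 10-year CVD risk models on a synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdcompare)
```

## The problem

Ten-year cardiovascular risk equations drive primary-prevention decisions:
whether a clinician starts a statin often reduces to whether a model's
predicted risk crosses a threshold. The major equations were derived on
North American and European cohorts, and when they are applied elsewhere
they can disagree sharply — not only about individual risks, but about what
fraction of a population is "high risk" at all. `cvdcompare` operationalizes
that comparison: score one cohort under six models, categorize under two
threshold conventions, apply each model family's statin rule, and quantify
concordance and discordance.

## The risk models

All six models share the structure: a linear predictor
$LP = \sum_k \beta_k f_k(x)$ over transformed covariates, pushed through a
risk transform. Cox-form models use the baseline-survival transform

$$p = 1 - S_0^{\exp(LP - c)}$$

with $S_0$ the 10-year event-free probability at the centering profile and
$c$ the derivation cohort's mean linear predictor. The revised
pooled-cohort-style model (`apce`) is logistic: $p = (1 + e^{-LP})^{-1}$.

Coefficients are *data*: one YAML file per model stratum under
`inst/extdata/models/`, validated on load against a closed covariate and
transform vocabulary, with a checksum over the coefficient block so a silent
edit of a single coefficient is caught. Term factors multiply, which covers
every published pattern used here — log and squared-log transforms,
products of transformed covariates (e.g. $\ln a \cdot \ln \mathrm{SBP}$),
squared terms, and three-way products. Treated and untreated SBP are two
mutually exclusive covariates: the transformed SBP multiplied by the
treatment (respectively no-treatment) indicator.

Two modelling decisions were genuinely open:

- **Ancestry stratum.** The PCE is ancestry-stratified and the revised
  equations carry an ancestry indicator, but nothing in a cohort file says
  which stratum to apply. `score_cohort()` defaults to the Black/African-
  American coefficient set — appropriate for the Haitian target population —
  and logs the choice on every run; it is overridable per run, never hidden.
- **Revised-equation variant.** The shipped `apce` config encodes the
  revised logistic equations *without* their optional recalibration
  constants; the config's source field records this so the choice is
  swappable by editing data, not code.
- **WHO-style models.** The original region-recalibrated coefficient tables
  for the WHO chart models were not available for transcription. The shipped
  `who_lipids`/`who_bmi` configs are **synthetic stand-ins**, labelled as
  such in the files themselves: sex-stratified Cox models in the WHO
  functional form and units (mmol/L lipids; the non-laboratory version uses
  BMI and drops diabetes), with coefficient magnitudes and baseline
  survivals anchored so typical chart profiles land in chart-like risk
  bands. They exercise every pipeline path the true models would; they are
  not clinical instruments.

Internal canonical units are mg/dL and mmHg. A spec declaring mmol/L gets
converted at evaluation time (factor 38.67 for cholesterol), so no value is
ever converted twice.

Ages outside a model's published validity range are scored and flagged
(`age_out_of_range`), never clamped silently: the analytic population is
40+ but the models' ranges differ, and dropping or clamping would silently
change cohort-level summaries.

### A non-monotonicity worth knowing about

The published PCE women's strata contain large negative
$\ln(\text{age}) \times \ln(\text{SBP})$ interaction coefficients. A
consequence — verified against an independent transcription, so it is a
property of the source equations, not of this implementation — is that for
women with low HDL and high (especially treated) SBP, predicted risk can
*decrease* as age increases. The test suite asserts monotonicity in SBP and
smoking for all six models and in age for the other five, and pins the PCE
quirk with an explicit counterexample so any future coefficient edit that
changes the behaviour is noticed.

## Cohort preparation

Blood pressure follows the measurement protocol of seated triplicate
readings: the first reading is discarded and readings two and three are
averaged; that average is the SBP used everywhere downstream. The analytic
sample is built by a sequential exclusion cascade — incomplete model inputs,
then age < 40, then current statin use, then prior MI/stroke — with each
record counted once at its first failing step, mirroring the mutually
exclusive counts of a cohort flow diagram. Filtering is idempotent and
order-equivariant, both property-tested.

Hypertension (used only for risk-factor counting in the Framingham statin
rule) is defined as antihypertensive treatment OR averaged SBP >= 140 mmHg
OR averaged DBP >= 90 mmHg. DBP is assumed averaged the same way as SBP.
Missing family history of premature coronary disease defaults to absent
with a warning, since cohort instruments often omit it while the Framingham
rule needs it. Complete-case analysis only; no imputation.

## Categorization and discordance

Two threshold schemes: uniform (low < 5%, intermediate 5 to < 7.5%, high
>= 7.5% for every model) and model-specific (PCE-type 5%/7.5%; Framingham
10%/20%; WHO 5%/20%). Bands are left-closed and right-open with the top
category closed at its cut: a risk of exactly 7.5% under the PCE is high,
exactly 5% under a WHO model is intermediate. The sources write the high
band as ">= cut", which forces this reading at the upper cut; the lower cut
is treated symmetrically. This is the package's documented convention, not a
claim about any particular study's tie handling. Risks are compared at full
precision — rounding to whole percents first would misclassify
boundary-adjacent scores.

Discordance is deliberately extreme: a participant is discordant only if
some model calls them *low* while another calls them *high*. The pattern
tabulation records which models called high and which called low for each
discordant participant.

## Statin rules

Three families, each a disjunction evaluated in published order with the
first satisfied criterion recorded (the recorded code is reporting metadata;
eligibility itself is order-invariant):

- **PCE family** (applies to `pce`, `apce`): LDL >= 190; or diabetes with
  LDL >= 70; or risk >= 7.5% with LDL >= 70.
- **Framingham family**: LDL >= 190; or diabetes with LDL >= 100; or risk
  >= 20% with LDL >= 100; or risk in [10%, 20%) with LDL >= 130 and >= 2
  risk factors; or risk < 10% with LDL >= 160 and >= 2 risk factors. The
  10–20% band is half-open so criteria 3–5 partition the risk axis. Risk
  factors: smoking, hypertension, HDL < 40, premature family history, and
  the sex-specific age cut (45 for men, 55 for women) — at most five can
  co-occur since the two age criteria are mutually exclusive.
- **WHO**: risk >= 20%, which by construction coincides exactly with the
  WHO models' high category under model-specific thresholds (asserted
  exactly in the tests).

Participants already on statins never reach these rules; the exclusion
cascade removes them upstream.

## Comparison statistics

Spearman rank correlations (average ranks for ties) measure concordance of
the models' risk *orderings*; the implementation delegates to
`stats::cor(method = "spearman")` and is cross-checked in the tests against
an explicit rank-then-Pearson computation. Categorical tables are compared
with Pearson chi-square tests of independence without continuity correction
(`stats::chisq.test(correct = FALSE)`, cross-checked against
$\sum (O-E)^2/E$); this variant reproduces the published statistic (1416)
for the reference 6x3 category count table shipped in
`inst/extdata/published_counts.csv`. Proportion intervals are Wilson score
intervals without continuity correction (`stats::prop.test(correct =
FALSE)`, cross-checked against the closed form); this variant reproduces
the published intervals for 563/1345 (39.2–44.5%) and 24/1345 (1.2–2.6%)
at one-decimal rounding, which the continuity-corrected variant does not.
Quantiles everywhere use linear interpolation (R type 7), so high-risk
profile tables are reproducible. P-values are reported as computed; since
reference values are printed only as "< 0.001", tests assert bounds.

## The synthetic cohort generator

The study population's participant-level data are not publicly deposited,
so the generator stands in for them. It is a Gaussian copula: each
participant is a row of a latent multivariate normal with a configured
correlation matrix (checked positive semi-definite), and each observed
variable is a monotone map of its latent coordinate:

- **Age**: a two-piece lognormal above a hard floor of 40, hitting the
  target quartiles 47 / 54 / 62 exactly in distribution. The floor encodes
  that the generator emulates the *analytic sample*, not full enrollment.
- **SBP**: normal, location/scale solved from the two published cut-point
  prevalences (>= 130: 54.7%; >= 140: 39.8%). Three readings are emitted by
  adding independent N(0, 4 mmHg) measurement noise to the participant-level
  truth; the truth's scale is deflated by the averaging-noise variance so
  the *averaged* SBP hits the targets. DBP is analogous (>= 80: 47.9%;
  >= 90: 25.9%).
- **Lipids and BMI**: lognormal, with medians and log-scales solved from the
  published cut-point prevalences (HDL < 40: 21.0%; LDL >= 130: 33.5%;
  BMI >= 30: 21.8%). Total cholesterol is LDL + HDL + a lognormal VLDL
  remnant (median 25 mg/dL) rather than an independent draw, so the lipid
  panel is internally consistent.
- **Binary variables** (sex, diabetes, smoking, treatment, family history,
  HIV): upper-tail thresholds at the target prevalence, so marginals are
  hit exactly in distribution regardless of the correlation structure.

The latent correlations (age–SBP 0.35, SBP–DBP 0.70, modest lipid and BMI
links, women smoking less and carrying higher HDL) are a modelling choice —
no joint distribution is published — chosen so that discordance patterns are
non-trivial rather than an attempt to reproduce the real cohort's joint
structure. The treatment–BP correlations (0.30 with SBP, 0.13 with DBP)
were solved once so that the *derived* hypertension prevalence (treatment OR
SBP >= 140 OR DBP >= 90) lands on its 52.9% target; hypertension is the one
marginal that is a function of three others, so it is the one place a free
parameter had to be fitted.

What passing marginal-recovery tests show: every targeted prevalence is
recovered within 3 binomial standard errors at n = 10 000 across 5 seeds,
and generated cohorts pass ingestion and the exclusion cascade untouched.
What they do not show: anything about the real cohort's joint distribution,
its continuous distribution shapes away from the published cut-points, or
its exact downstream category/eligibility tables. Pipeline results on
synthetic cohorts are regime-level emulations, not reproductions.

## Numerical and testing choices

Double precision throughout; the engine is deterministic and has no
stochastic elements — all randomness lives in the generator and is a pure
function of the seed. Each model's engine output is pinned to an
independently typed second transcription of its coefficient table at 1e-6
relative tolerance on fixed reference profiles, and published worked
examples reproduce (e.g. 10.48% under the lipid Framingham equation for its
reference profile). Discordance and category tallies are tested against
brute-force scans; the Wilson and chi-square implementations against closed
forms. Default problem sizes in the test suite (10 000-row marginal checks,
1000-profile monotonicity sweeps, 500 x 6 brute-force discordance) keep the
full suite under a minute while leaving Monte-Carlo margins comfortable.

## Known limitations

- The WHO-style coefficient sets are synthetic stand-ins (above); WHO-model
  absolute risks should not be interpreted clinically.
- The revised-equation recalibration constants are not applied.
- The generator's continuous distribution shapes (lognormal lipids, normal
  pressures, two-piece lognormal age) are conventional choices constrained
  only at the published cut-points.
- No observed-event data: calibration and discrimination against outcomes
  are out of scope by design, as is any refitting of coefficients.
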