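---
title: "Evaluating facility accreditation with DiD and kernel PSM: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating facility accreditation with DiD and kernel PSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facdid)
```

## The evaluation problem

A national accreditation program certifies primary-health-care
facilities in phases: districts are selected over several years, the
most deprived (as measured by a social vulnerability index built from
eight census indicators) first. Facilities in a selected district are
surveyed and granted full accreditation (total score at or above 80%),
provisional accreditation (50% to just under 80%) or denied (below
50%); `classify_accreditation()` implements this three-tier rule with
the half-open convention `[0.50, 0.80)` for provisional so the
partition is exhaustive. Both full and provisional facilities count as
treated throughout the package, and facilities that simultaneously
received other reform interventions (performance-based financing, user
fees) are excluded by `apply_sample_rules()` so the treatment contrast
reflects accreditation alone — the flag removes *accredited* facilities
only, since a never-accredited facility with such interventions is
still a valid control for the accreditation contrast.

Outcomes come from repeated household surveys. Each respondent is
linked to her nearest facility by great-circle distance (haversine,
sphere radius 6371.0088 km); there is no distance cutoff by default,
reflecting catchment-area obligations, and ties are broken by lowest
facility id so linkage never depends on input order. Outcomes are then
collapsed to facility-level percentages over outcome-specific
denominators (contraceptive users, recent mothers, mothers of young
children).

## Estimators and their assumptions

**Fixed-effects DiD** (`fit_did_fe`) removes facility-constant
confounding and common shocks; identification rests on parallel trends
between eventually-treated and never-treated facilities. The estimator
is the within transformation: outcome, policy and wave dummies are
demeaned by facility and the policy coefficient obtained by OLS, which
is numerically identical to a regression with a dummy per facility (a
test enforces agreement to 1e-8). If policy never varies within any
facility the model is unidentified and the function says so explicitly
rather than returning a number.

**Two-period DiD** (`fit_did_2period`) contrasts a baseline and a
follow-up wave on facilities observed in both, with facility controls
(eight staff-category counts, building condition with reference
"bad", catchment population) and district controls (the eight
indicators plus region dummies with reference "fully-urban").
Treatment here means *accredited by the follow-up wave*; facilities
entering the program later are controls for that period pair. This
matters: labeling all eventually-accredited facilities as treated
dilutes the contrast with units that carry no effect yet. Collinear
covariates are dropped with a warning naming them, never silently.

**Kernel PSM-DiD** (`psm_did`) addresses selection on the observables
that drove targeting. A logistic model of treatment on the district
indicators is fit by iteratively reweighted least squares
(convergence when the largest coefficient change falls below 1e-8,
at most 100 iterations; covariates are standardized internally for
stability and coefficients returned on the original scale). Perfect
separation is detected — diverging coefficients with fitted
probabilities pinned at 0 or 1 — and reported as an error naming the
worst covariate, because a separated propensity model produces
degenerate weights, not estimates. Common support uses the min-max
rule; units outside are excluded and counted. Each treated facility's
counterfactual change is a kernel-weighted average of control changes,
Epanechnikov by default, and the overall estimate averages treated
facilities with equal weight (an option weights by catchment
population). The remaining identification assumption is parallel
trends *conditional on the matched support*.

### Inference

Treatment is assigned at the district level, so standard errors
cluster at the district level by default (`cluster_level =
"facility"` is available). The covariance is the CR1 sandwich —
within-cluster score outer products scaled by `G/(G-1) × (N-1)/(N-K)`,
with `K` counting absorbed facility effects — and p values use
t(G−1). With singleton clusters the formula reduces to HC1, which is
tested against an independent implementation. The matching estimator's
standard error comes from `bootstrap_se()`, a district-level cluster
bootstrap that re-runs propensity fit, support, weights and the
estimate inside every draw, so matching-step uncertainty is included;
duplicated clusters get fresh pseudo-ids so their facilities are not
merged, and a draw failure rate above 20% (for example, loss of
overlap) is an error rather than a silently shrunken interval.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| kernel / bandwidth | Epanechnikov, 0.06 | propensity scale | the conventional pairing in applied kernel matching; both configurable since neither is dictated by theory |
| min denominator | 5 | eligible women per cell | facility percentages from 1–4 respondents are noise; masked cells keep their denominators for accounting |
| cluster level | district | — | the treatment-assignment level; the conservative convention |
| max linkage distance | none | km | catchment obligation; a cutoff flag exists and logs drops |
| GPS jitter | 2 | km (SD, isotropic) | survey-style location blurring around the true facility |
| facility spacing | 12 | km minimum | keeps nearest-facility linkage correct for ≥99% of women at the default jitter; the mis-linkage rate is reported by the pipeline |

## What the generator emulates — and what it does not

`truth_config()` fixes the whole generative law: eight district
indicators from Beta/Gamma/log-normal distributions; facilities
scattered around district centroids with the minimum spacing above;
district selection probability `plogis(qlogis(target_share) +
targeting_strength × vulnerability)` with the most vulnerable selected
districts entering at the earliest rollout waves; and woman-level
binary outcomes with log-odds = baseline + wave effect + facility
intercept + treatment shift. Facility intercepts are Gaussian
(sd 0.3) plus `confounding_strength` (default −0.5) times the
district's vulnerability index. That last term is essential to the
package's own validation: it creates selection on outcome *levels*
(not trends), which biases a naive post-period contrast while leaving
DiD-type estimators consistent — exactly the failure mode matching
plus differencing is meant to fix. The vulnerability index itself is
the mean of the eight z-standardized indicators, deprivation
indicators signed positive and population size negative (larger
districts read as less vulnerable); the signs are configurable because
no single convention is canonical.

Planted effects are specified in percentage points and converted to a
log-odds shift by solving
`E_b[expit(η+b+s)] − E_b[expit(η+b)] = effect/100` with Gauss–Hermite
quadrature over the facility intercept distribution
(`planted_logit_shift`). A plain conversion at the baseline alone is
attenuated by the logistic curvature once heterogeneity is present
(about 0.2 ppts at a 10-ppt effect with sd 0.3); the marginal
calibration makes the model-implied infinite-n DiD equal the
configured effect, which is what recovery tests should target. With
`facility_sd = 0` it reduces to the plain conversion.

Two sampling routes share one probability law: `gen_women()` draws
individual records (for linkage and collapsing tests), and
`gen_facility_panel()` draws the collapsed facility×wave panel
directly via binomial counts — the exact distribution of the
woman-level route after truth-based collapsing. The Monte-Carlo
studies use the collapsed route so hundreds of replicates stay cheap;
a test compares the two routes at matched configurations.

Not emulated: sampling weights and multi-stage cluster designs, real
geography, within-woman correlation across outcomes, facility entry
and exit, and the re-assessment of provisionally accredited
facilities. Passing tests therefore demonstrate correctness of the
estimators under a clean version of the assumed data-generating
process, not robustness to design-based survey features.

## Numerical and degenerate-input conventions

- Kernel weights for each treated unit are renormalized to sum to one;
  a treated unit with no control inside the bandwidth window is
  dropped with a log message, never silently zeroed.
- A control missing one of the two periods is removed from every
  weight vector, which is then renormalized; a treated facility
  missing a period is dropped and counted.
- Zero-variance covariates: the vulnerability index lets them
  contribute zero with a warning; the propensity fit drops them with a
  warning; balance tables report SMD 0 with a warning instead of
  dividing by zero.
- Duplicate (facility, wave) keys and links to unknown ids are
  data-integrity errors naming the offending id.
- All randomness flows from one master seed through named substreams
  (`substream_seed`), so stages re-run independently and full runs are
  byte-identical under a fixed config.

## Design choices that were genuinely open

- **Propensity covariates.** The eight district indicators, without
  region dummies, by default. Treatment varies only at the district
  level, so the effective propensity sample is the number of
  districts; adding five region dummies routinely produced perfect
  separation at realistic district counts. Region dummies can be added
  via `covariate_cols` when districts are plentiful.
- **Placebo form.** Both a fake-group mode (pseudo-treating whole
  never-treated districts, preserving the treated share and drawing
  pseudo-timing from the real rollout waves) and a fake-timing mode
  (pseudo-treating the actually-treated districts from a mid-pre-period
  wave) are implemented and labeled; fake-group is the default because
  it respects the assignment mechanism.
- **Pre-trend test form.** A group-specific linear trend on the
  pre-period waves (ppts per wave step, cluster-robust t), chosen over
  an event-study leads specification for stability with few pre-waves.
- **Unbalanced panels.** The fixed-effects estimator uses all
  available cells; the two-period estimators require both periods and
  log how many facilities that drops.

## Study sizes used by the validation suite

The package's own calibration and recovery studies (test suite and
`scripts/acceptance.R`) use: 500 facilities in 125 districts for
effect recovery (two waves, planted +10 ppts, confounded targeting)
and for pre-trend power (four pre-period waves, planted 2 ppts/wave);
the default 40-district configuration over six waves for type-I
calibration (200–400 null replicates); and 30 women per facility and
wave throughout — sizes chosen to mirror DHS-scale cluster counts
while keeping hundreds of replicates comfortably runnable on one CPU.

## Known limitations

- Staggered adoption is estimated with the classical two-way
  fixed-effects model; heterogeneity-robust staggered-DiD estimators
  are deliberately out of scope, so strongly time-varying effects can
  be averaged with negative weights.
- Analytic standard errors for the matching estimator ignore the
  estimated-propensity step; use the bootstrap for final inference.
- The linkage assumes respondents use their nearest facility;
  road-network travel times and deliberate bypassing are not modeled.
- Multiple outcomes are reported without multiplicity adjustment,
  matching common applied practice; adjust externally if needed.
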