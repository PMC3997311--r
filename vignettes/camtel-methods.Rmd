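---
title: "Methods: testing the consistency of camera-trap and telemetry space use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the consistency of camera-trap and telemetry space use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtel)
```

## The scientific problem

Spatial capture–recapture and related density estimators combine camera-trap
detections with telemetry under the assumption that both measure the same
space-use process. `camtel` tests that assumption directly. Telemetry gives
each animal a utilization distribution (UD) — the probability density of its
space use. If cameras sample the same process, the hazard of photographing a
given animal at a given camera should be proportional to the UD at the
camera's location. Departures from proportionality (systematic attraction to
core areas, trap responses, sex-specific movement effects) appear as better
support for more complex models.

## Detection models

For an animal × camera record $i$ with exposure $T_i$ days, the linear
predictor is the log capture rate

$$\eta_i = \beta_{Sex(i)} + \beta_{UD}\,\log UD_i + \dots$$

giving the rate $\lambda_i = e^{\beta_{Sex}} UD_i^{\beta_{UD}}$ and, for a
binary detected/not-detected response,

$$\pi_i = 1 - \exp(-\lambda_i T_i),$$

the inverse complementary log-log link. The cloglog link is the natural
choice here — detection over an interval is the complement of a Poisson zero
count, which is what a spatial encounter process produces — rather than the
conventional logit. Photo counts use the same predictor with a log-link
Poisson (or quasi-Poisson) family.

Proportionality ($\beta_{UD} = 1$) is imposed by an *offset*: the term
$1 \cdot \log UD_i$ is forced into the predictor with no estimated
coefficient. The *simple model* is therefore `Sex + offset(logUD)`. Because
the offset model is the free-exponent model constrained to
$\beta_{UD} = 1$, its maximized log-likelihood must equal the free model's
likelihood function evaluated at the offset solution with $\beta_{UD}$ set
to 1 — `offset_consistency_check()` verifies this identity (to numerical
precision, ≤ 1e−8) and reports the free estimate with its Wald interval.

By default count and cloglog models also carry `offset(log T_i)`, so
deployments of unequal length are comparable on the rate scale; set
`exposure_offset = FALSE` to mirror designs with roughly equal windows. The
logit-link proximity models omit it (a rate offset has no logit-scale
interpretation).

### Candidate sets and selection

The home-range candidate set contains the simple model, an intercept-only
offset model, free-exponent models (`Sex + logUD`, `Sex * logUD`,
`Isopleth + logUD`), additive and interactive `Core`/`Isopleth` models on
top of the offset, and no-UD models (`Sex + Isopleth`, `Sex * Isopleth`).
`Isopleth` is the camera's isopleth percentile scaled to $[0,1]$; `Core` is
the indicator of the 50% region. Binary GLMs are compared by AICc
($\mathrm{AIC} + 2K(K{+}1)/(n{-}K{-}1)$), quasi-Poisson count models by
QAICc ($-2\ell/\hat c + 2K + 2K(K{+}1)/(n{-}K{-}1)$ with $K$ counting the
estimated dispersion $\hat c$), mixed models by AIC. $\hat c$ is the Pearson
$\chi^2/\mathrm{df}$ of the saturated fixed-effects model, floored at 1 for
QAICc and reused across the family. Akaike weights are
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$; ties break by smaller $K$,
then label.

$K$ conventions, stated so tables are comparable: intercepts are counted;
each random-effect variance adds 1; QAICc adds 1 for $\hat c$. Thus the
simple binomial GLM has $K = 2$ and its quasi-Poisson counterpart $K = 3$.

Random-effect structures (`(1|Fisher)`, `(1|Camera)`, `(1|Fisher/Camera)`)
are selected first, with saturated fixed effects, before fixed effects are
compared (`select_random_effects()`); this two-stage protocol is
deterministic given the data. Mixed fits use the Laplace approximation
(lme4), cross-checkable against adaptive Gauss–Hermite quadrature (`nagq`)
for a single grouping factor. Because the cloglog inner PIRLS iteration is
fragile when offsets span many log-units, mixed fits start from the
fixed-effects GLM solution (`nAGQ0initStep = FALSE`, bobyqa). Quasi
families are fitted at the base family, so their point estimates equal the
non-quasi fit exactly and SEs scale by $\sqrt{\hat c}$. For mixed models,
`conditional_r2()` implements the Nakagawa–Schielzeth measure with
distribution variance $\pi^2/3$ (logit), $\pi^2/6$ (cloglog), or
$\log(1 + 1/\bar\lambda)$ (log link; log-normal approximation, with
$\bar\lambda$ the mean fitted count — the literature offers no single
convention here, so the choice is documented rather than hidden).

### Proximity analysis

Independently of home ranges, `run_proximity_analysis()` predicts binary
detection from the number of relocations within 250 or 500 m of the camera
(`NLocs`), `Sex`, `Season` and their interactions, with a per-animal random
intercept. The 500-m cap matters: with cameras on a 1-km grid, disks of
500 m cannot overlap, so each relocation is counted for at most one camera
(the builder warns when a radius exceeds half the minimum camera spacing).
These models default to the logit link — the analysis is a descriptive
efficacy check rather than an encounter-rate model — with the link exposed
as an argument.

## Home-range estimation

`estimate_ud()` computes a fixed-kernel (single global bandwidth) Gaussian
KDE on a regular grid. The reference bandwidth is the bivariate-normal rule
$h_{ref} = \sqrt{(s_x^2 + s_y^2)/2}\, n^{-1/6}$ with a single isotropic
smoothing parameter. Because the reference rule oversmooths multimodal
ranges, `select_bandwidth()` scans multipliers 0.6–0.9 of $h_{ref}$
(ascending) and returns the smallest that passes two criteria,
operationalized from qualitative practice with exposed defaults:

* **cohesion** — the 90% and 95% isopleths break into at most
  `max_fragments = 3` connected components (4-connectivity; a conservative
  fragment count);
* **extent** — those isopleths extend at most `extent_margin = 2`
  bandwidths beyond the relocation bounding box on every side;

falling back to the full reference bandwidth (multiplier 1.0) when all
candidates fail.

Numerical choices: grid cell $h/4$ (a guard rejects cells larger than
$h/2$), margin 3 bandwidths around the data, and the grid is renormalized
so that $\sum z \cdot \mathrm{cell}^2 = 1$ exactly. The renormalization is
deliberate: with a 3-bandwidth margin the raw Riemann sum can lose a few
parts per thousand of corner mass, and downstream isopleth mass accounting
assumes an exact unit total. Isopleth thresholds come from grid mass: cells
are ranked by density and the threshold for $p$% is the density of the
first cell at which cumulative mass reaches $p$% (mass, not polygonized
area — the convention is stated because historical GIS tools do not
document theirs). Membership ("inside the 90% isopleth") is likewise by
grid density at the point, interpolated bilinearly (`ud_at()`), with points
beyond the grid assigned density 0. All analyses truncate home ranges at
the 90% isopleth, where kernel tails are least reliable.

Seasons: *Fall/Winter* = 1 October–15 March, *Summer* = 1 June–30
September, both inclusive; 16 March–31 May (the reproductive season) is
excluded pipeline-wide before any stage. Seasonal UDs require at least 25
relocations, annual UDs 5 (both configurable).

## The synthetic-data generator

`sim_config()` fixes the study conditions; they are calibration choices,
not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_females`, `n_males` | 20, 10 | cohort of collared animals, F-skewed |
| `sigma_female` | 1243 m | 95% kernel area of an isotropic Gaussian range = 2910 ha |
| `range_scale_male` | 3.06 | male/female annual area ratio (8915.8 / 2910.0 ha) |
| `relocs_per_week` | 5 | aerial relocation 4–6 days/week |
| `telemetry_error_sd` | 338.9/√(π/2) ≈ 270 m | mean radial error 338.9 m (Rayleigh mean σ√(π/2)) |
| `camera_cell`, `camera_jitter` | 1000 m, 150 m | cameras near centres of 1-km grid cells, spacing ≥ 700 m |
| `deployment_length_days` | 36 | 32–40 day deployment windows |
| `beta_f`, `beta_m` | 12.5, 13.2 | detection rates of ~20% overall and ~40% at high-use cameras, matching reported detection probabilities of 0.3–0.8 at active cameras; males more detectable at equal UD |
| `beta_ud` | 1 | the proportional model |

Home ranges are stationary Gaussian mixtures of 1–3 components (weights
Dirichlet-distributed, mild anisotropy and per-component area jitter).
The analyses use only marginal space-use frequency — exactly what a kernel
home range measures — so trajectory autocorrelation is intentionally out of
scope. Male covariances are `range_scale_male` times female covariances and
male component offsets scale by its square root, so the expected male/female
*area* ratio equals `range_scale_male` exactly. The "true" UD at a camera is
the mixture density evaluated at the camera point (continuous, not a grid
lookup), so kernel estimation error is a measurable property of the
pipeline. Relocations are mixture draws plus isotropic Gaussian error, one
per sampled day; detection counts for each animal × camera are Poisson with
mean $\lambda T$ over the pair's exposure (deployment ∩ tracking, excluded
season removed), and event timestamps are uniform over exposure days.
Monte-Carlo helpers (`true_isopleth_threshold()`, `true_isopleth_pct()`,
`true_isopleth_area()`) exploit the identity that the $p$% threshold of a
density $f$ is the $(1-p/100)$ quantile of $f(X)$, $X \sim f$.

Overdispersion is induced, when requested, by a unit-mean gamma frailty
shared within each animal × camera pair — the heterogeneity that motivates
the `(1|Fisher/Camera)` random effect. Its shape is calibrated by bisection
against the analytic expected saturated-model Pearson dispersion
$1 + \overline{\mu}/a$ (exact for Poisson–gamma mixtures), evaluated on the
available-pair means. A caveat discovered by the package's own tests: with
many rows whose expected counts are ≪ 1 the Pearson estimator is biased
slightly low; dispersion validation therefore uses configurations with
moderate expected counts (intercepts 13.6/14.3), the estimator's intended
regime.

What the generator does *not* emulate: movement autocorrelation, trap
responses (trap-happiness/shyness), bait depletion, den-season behavioural
shifts, camera failure, or multi-animal interactions at traps. Passing
recovery tests therefore demonstrate internal statistical consistency of
the method, not robustness to these real-data phenomena.

Determinism: a single global seed; every stage draws from a deterministic
substream (`population`, per-animal `relocations`, `cameras`,
`detections`, replicate loops), so identical configurations reproduce
byte-identical outputs.

## Encounter tables

A camera is *available* to an animal in a season when its deployment
overlaps the animal's tracking window with at least one non-excluded day of
that season and (for the home-range analysis) the camera sits inside the
animal's 90% isopleth. Records straddling a season boundary are split into
per-season rows with the corresponding exposure, avoiding mixed-season
covariates. Proximity counts are restricted to the record's season and
overlap window, keeping covariate and response contemporaneous (a
documented design choice; the year-cumulative alternative is equally
defensible). Detection events group images of one animal at one camera
separated by at least 15 minutes; unidentifiable photos are modelled in the
simulator as an optional per-event dropout and simply dropped (never
imputed) in table building, with dropped-image counts reported. Every table
build runs `validate_encounters()`: positive exposure, `core ⇔ isopleth ≤
50`, `detected ⇔ photo_count ≥ 1`, `NLocs250 ≤ NLocs500`.

## Recovery experiments and problem sizes

`run_recovery_experiment()` closes the loop: simulate → build table → fit
free-exponent and offset models → aggregate bias, RMSE, Wald-CI coverage
and AICc win frequencies across replicates. Two UD sources are compared:
the true mixture density (estimator calibration) and the fixed-kernel
estimate from simulated telemetry (attenuation from home-range estimation
error; its magnitude is reported, not asserted).

The shipped tests exercise the stack at sizes chosen to make Monte-Carlo
error small relative to the effects checked while keeping a full run in a
couple of minutes: 100-replicate recovery and selection studies on 15–40
animal populations (≈ 500–1400 rows per replicate), 10^5 draws for the
closed-form detection check, 2000-point kernels for the Gaussian
calibration, and 50-replicate dispersion calibrations. The same sizes are
used by `scripts/acceptance.R`.

## Known limitations

* Stationary mixtures mean no within-season range shifts; seasonal
  differences arise only through sampling windows.
* The isopleth covariate of simulated tables is computed by Monte Carlo
  from the true density (1% granularity), while pipeline tables derive it
  from the kernel surface; the two agree only up to kernel estimation
  error.
* Wald intervals only (no profile likelihood); `U`-statistic home-range
  comparisons use exact enumeration only for groups ≤ 20 without ties.
* GLMM support is restricted to random intercepts; crossed random slopes,
  spatially explicit capture–recapture likelihoods and Bayesian fitting are
  out of scope.
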