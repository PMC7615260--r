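---
title: "Attributing childhood anemia burden to ambient warming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing childhood anemia burden to ambient warming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Childhood anemia (altitude-adjusted hemoglobin below 11 g/dL in children
under five) is highly prevalent across sub-Saharan Africa, and ambient
temperature plausibly influences it through malnutrition and malaria
pathways. `climanemia` implements a complete attribution pipeline for this
question: estimate how the odds of anemia change per +1 °C of annual mean
temperature in clustered survey microdata, convert that association to a
risk scale, decompose it through mediators, bias-correct climate-model
temperature projections, and translate scenario warming into excess anemia
cases per 100,000 person-years.

Because individual-level health-survey microdata of this kind are
access-restricted and reanalysis/climate-model archives are enormous, the
package ships a first-class synthetic-data module. Every generator is
seeded and emits machine-readable generating truth, so the whole pipeline
is testable end-to-end: parameter recovery, mediation recovery,
bias-correction exactness and closed-form burden checks are all asserted
in the test suite rather than taken on faith.

## The association model

The main model is a mixed-effects multivariable logistic regression at the
child level:

$$\mathrm{logit}\,P(\text{anemia}_i = 1) = \beta\, T_i + \gamma' X_i + u_{c(i)},
\qquad u_c \sim N(0, \sigma_c^2),$$

where \(T_i\) is the mean daily temperature over the 365 days preceding
the child's interview (windows of 1, 3, 6 and 9 months are available for
sensitivity fits), \(X_i\) collects child covariates (age band, sex,
continuous BMI, bednet use), maternal covariates (age band, education),
household covariates (residence, multiple children, water source,
sanitation, floor and roof material, asset-based wealth quintile), climate
covariates (annual cumulative precipitation and the trailing decadal mean
temperature, which isolates the effect of year-to-year temperature
anomalies from long-run climatological differences between places),
country-level covariates (crop-production index, GDP per capita) and
survey month and year as categorical terms, and \(u_c\) is a random
intercept for city (the admin-2 unit containing the cluster).

Estimation uses `lme4::glmer` (maximum likelihood, Laplace approximation,
BOBYQA optimizer). A fixed-effects fallback (`method = "glm"`) with
city-clustered sandwich standard errors is exposed for small fixtures and
resampling loops; at moderate sizes the two engines agree closely and the
fallback is what the bootstrap uses internally. `nAGQ = 0` is available as
a faster, slightly cruder option for exploratory fits; its Wald intervals
are not used for calibration claims because they undercover at small
sample sizes.

The wealth index follows standard survey practice: the first principal
component of the standardized household asset battery, computed within
survey, oriented so more assets score higher, and cut into within-survey
quintiles with deterministic tie-breaking.

### From odds to risk

Anemia is common (around 64% prevalence), so odds ratios overstate risk
ratios. With country prevalence \(\mathit{Rate}_c\), the package converts

$$RR_c = \frac{OR_c}{1 - \mathit{Rate}_c + \mathit{Rate}_c \times OR_c},$$

applied to the point estimate and to each confidence bound (the map is
monotone in OR). The excess risk coefficient used for attribution is
\(ERC_c = RR_c - 1\), a fraction per +1 °C; keeping it a fraction (not a
percentage) makes the burden formula dimensionally yield cases.

### Exposure-response shape

A natural cubic spline (3 df) in temperature replaces the linear term to
depict the exposure-response curve; an ANOVA F test between the nested
quasibinomial fits tests departure from linearity. The curve is reported
as centered log-odds on a temperature grid with a pointwise 95% band.

## Mediation

Mediation through child malnutrition (Kaup index — BMI in young children —
below 15 kg/m²) and malaria infection (positive rapid diagnostic test)
uses the difference-of-coefficients estimator: the total effect (TE) is
the temperature coefficient of the main model, the direct effect (DE) is
the same coefficient after adding the mediator, the indirect effect is
\(IE = TE - DE\), and the percentage mediated is \(100 \times IE/TE\)
(reported as undefined when \(|TE| < 10^{-6}\)). Empirical 95% CIs come
from a seeded percentile bootstrap with clusters resampled with
replacement — the resampling unit respects the survey design; individual
resampling is available as an option. Both fits always use the identical
complete-case rows, so adjusting for the mediator never changes n.

Two deliberate modeling choices here:

* The mediation fits exclude the continuous-BMI covariate. The
  malnutrition mediator is a deterministic threshold of BMI, so
  conditioning on exact BMI in the TE model would block that pathway by
  construction and force \(IE \approx 0\). Dropping BMI from both fits
  makes the decomposition well-defined.
* The mediation fits use city fixed effects in place of the random
  intercept. Inside a resampling loop this is both fast and stable, and it
  absorbs city-level heterogeneity in every refit; at these cluster
  counts, conditional estimates from the two parameterizations agree.

Difference of coefficients on the log-odds scale is an approximation: the
odds ratio is non-collapsible, so TE − DE is exact only for modest
effects. The package documents rather than corrects this, and the
synthetic generator is calibrated in the same estimand (below), so tests
compare like with like.

## Climate projections

Pseudo-GCM daily temperature fields are processed in a fixed order:
**bilinear regrid to 1.0°** (cell-center interpolation; a plane is
reproduced exactly) → **additive-scaling bias correction** against the
regridded reference over the 1985–2014 baseline → **city aggregation**
(unweighted mean over cells whose centers fall in the admin-2 polygon,
nearest cell as a logged fallback for slivers) → annual means.

Additive scaling computes, per grid cell and calendar month, the
climatological offset between model and reference over the calibration
window and subtracts it everywhere:

$$\mathrm{corrected}(t) = \mathrm{gcm}(t) - \overline{\mathrm{gcm}}_{m(t)} + \overline{\mathrm{ref}}_{m(t)}.$$

Monthly offsets are the standard dialect of the delta method; an annual
single-offset variant is exposed via `granularity`. Offsets are purely
additive, so variance and future trends pass through untouched and the
correction is idempotent. Calibration overlap below 20 years warns; below
5 years it errors.

City-year warming is
\(\Delta T = \text{annual mean} - \text{baseline mean (1985–2014)}\),
per ensemble member and scenario. The baseline window is 1985–2014
throughout (the attribution baseline) and is exposed as an argument.
All daily series use a 365-day calendar — leap days are dropped once at
generation so model and reference axes align without special cases.

## Burden attribution

For each city, year, ensemble member and scenario:

$$\text{Excess cases} = \mathit{Pop}_c \times \mathit{Rate}_c \times \mathit{ERC}_c \times \Delta T,$$

with the city's under-5 population, the country's survey prevalence and
excess risk coefficient, and the city's warming. A decade's value is the
mean of its annual values; the point estimate is the mean across ensemble
members at the central coefficients; normalization to cases per 100,000
person-years divides by the scope's baseline under-5 population (the
no-population-change assumption of the main analysis). The
future-population variant scales the numerator by decade- and
scenario-specific under-5 populations while keeping the baseline
denominator, so the two variants coincide exactly for time-constant
population grids. Negative excess from cooling city-years is kept, not
truncated. City excess sums exactly to country, region and total excess
before normalization.

Uncertainty: 1,000 Monte Carlo draws of each country's log-odds
coefficient from \(N(\hat\beta_c, se_c)\) (independent across countries,
matching per-country fitting), each rebuilt into an ERC through the
OR-to-RR conversion, recomputed for every ensemble member, pooled, and
summarized by the 2.5th/97.5th percentiles. Burden is linear in the
per-country ERC, so draws reuse precomputed aggregates and the Monte
Carlo step costs almost nothing. Decade labels are calendar decades
("2090s" = 2090–2099).

## The synthetic world

The generator lays countries out as adjacent 3°×3° rectangles, each split
into rectangular admin-2 "cities". The reference climate has a planar
spatial climatology spanning 17–29 °C of country means, a shared seasonal
cycle (±3 °C), per-cell interannual anomalies (SD 0.5 °C — the variation
that identifies the temperature coefficient once decadal means are
adjusted for), and day-to-day noise (SD 1.5 °C). Precipitation is gamma
daily totals with a wet season, used only as an adjustment covariate.
Pseudo-GCMs are *warped references*: they share the reference weather and
add per-member, per-calendar-month biases (SD `gcm_bias_sd`) plus a
scenario warming ramp, linear in year from 2015, with per-member trend
multipliers (mean 1, SD 8%) supplying ensemble spread. The ramp slopes
are calibrated so the 2090s ensemble-mean warming equals 4.0, 2.2 and
1.1 °C for the high-, moderate- and low-emission scenario.

Survey microdata follow the two-stage cluster design: clusters uniform in
each country with one interview date per cluster (14-month fieldwork
windows so survey month and year vary within country), 8 binary household
assets driven by a one-factor latent wealth variable (strong loadings;
the PC1 score correlates about 0.87 with the latent factor — the
information ceiling of a binary battery), and the covariate schema of the
association model. Anemia is drawn from the mixed logistic model above;
hemoglobin is then drawn inside the severity band given by a
temperature-shifted conditional severity distribution, so
`anemia_status` is exactly `classify_anemia(hb_adjusted)` by
construction.

### Calibration of the generating truth

The quantities the pipeline is asked to recover are estimands of
*misspecified* fitted models (a marginalized mediator here, a blocked
pathway there), not raw generator coefficients. The generator therefore
calibrates three knobs at generation time against exact population-limit
coefficients, computed by probability-weighted IRLS on the realized
design (fitting expected outcomes instead of draws):

* the direct temperature coefficient is anchored so the **main model's**
  temperature coefficient equals `beta_temp` — the configured odds ratio
  is the estimand of the pooled fit;
* each mediator's temperature slope is anchored so the
  difference-of-coefficients **mediated proportion** equals the
  configured fraction (11.40% malnutrition, 9.74% malaria by default).

Five fixed-point iterations converge to well under a percentage point.
The achieved population-limit values are stored in
`truth$mediated_fractions_population_limit` for inspection. Country
intercepts are solved numerically so each country's expected prevalence
matches its target (baseline 63.76% plus recentered country offsets), and
the per-country targets are recentered so the equal-weight marginal
prevalence equals the baseline exactly.

### What the generator does not emulate

Sampling weights (the analysis is unweighted, matching the modeled
design), cluster-coordinate displacement, realistic geography or
coastlines, spatially correlated interannual anomalies, scenario ramps
that level off mid-century (ramps are linear), HemoCue measurement error,
and altitude adjustment (hemoglobin is generated already adjusted).
Passing tests therefore demonstrate that the estimators recover what they
claim under the stated statistical structure — not that real surveys are
free of the confounding, measurement and design problems these omissions
set aside.

## Numerical choices

* Severity thresholds partition the axis with half-open intervals:
  severe < 7.0, moderate [7.0, 10.0), mild [10.0, 11.0), none ≥ 11.0
  g/dL; hemoglobin outside 2–20 g/dL is flagged invalid and excluded with
  a warning. The 7.0–7.1 g/dL gap left by conventional rounding is
  resolved into the moderate class.
* Exposure windows are trailing day counts ending the day before the
  interview: `round(months × 30.4375)` days, except the 12-month window
  fixed at exactly 365 days. Windows are positions on the (leap-free)
  daily axis, so a window spanning February 29 does not silently shrink.
  Children under one can truncate the window at their birth date
  (`lifetime = TRUE`).
* Grid-to-point assignment is nearest cell center by default; bilinear
  interpolation is an option.
* Complete-case analysis within each fitted scope, with excluded-row
  counts messaged; factor covariates that collapse to one observed level
  are dropped from the formula.
* The internal bootstrap/calibration IRLS standardizes columns and adds a
  tiny ridge only when a resample empties a factor cell, pinning exactly
  the unidentified directions; full-rank fits agree with `glm.fit` to
  ~1e-9.
* Quintile ties break by row order (`ties.method = "first"`), making
  wealth quintiles deterministic.
* Degenerate inputs fail loudly and specifically: sites outside the grid
  list the offending ids, empty polygons name the city, a missing country
  fit names the country, zero-population cities are excluded from
  normalization with a warning.

## Problem sizes in the shipped tests

Module tests run on worlds of 360–8,000 children and toy analytic grids.
The end-to-end suite uses: 100,000 children (4 countries × 125 clusters ×
200 children) for parameter, mediation and window-ordering recovery; 200
replicates of 2,400 children for null-effect coverage; 200 replicates of
a 5-member single-country ensemble for burden coverage; a 20-member
ensemble for bias-correction exactness; and 40,000 children with a
strengthened severity-temperature gradient (a purpose-built world) for
the severity ordering. Bootstrap and Monte Carlo sizes in tests are 150–
200 draws; the acceptance script uses 200 bootstrap resamples and 1,000
coefficient draws. These sizes were chosen so the full pipeline exercises
at survey scale while a complete run stays comfortable on a laptop core.

## Known limitations

The cross-sectional design means the association is not causal evidence;
the linear exposure-response assumption is tested, not imposed by
necessity; difference-of-coefficients mediation inherits odds-ratio
non-collapsibility; the projection holds anemia patterns and adaptation
fixed, so projected burdens are upper-bound-flavored; and per-country
coefficient draws ignore cross-country correlation. The synthetic world's
rectangles and linear ramps are deliberately minimal — they validate the
machinery, not the geography.
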