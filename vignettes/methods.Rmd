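---
title: "Methods: line-transect abundance of harbor seals with availability corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-transect abundance of harbor seals with availability corrections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The estimation problem

Harbor seals are amphibious: at any instant some fraction of a stock is
hauled out ashore and another fraction is submerged on a dive, so an
aerial line-transect survey of seals *visible in the water* sees only the
available remainder. `sealcount` estimates in-water density from
perpendicular sighting distances and then scales up to total stock size
with an availability correction derived from seal-borne tags. The two
data streams — survey records and telemetry — are modelled separately and
joined only through the correction factor.

# Survey data treatment

Three filters define the analysis dataset (`filter_for_analysis()`), all
on by default: only systematic transect effort (connector and transit
legs are excluded because they run along shore or depth contours and are
not representative of the sampled density); only Beaufort sea states 0–2,
where small heads in the water remain sightable; and only segments
without hard glare (a per-segment boolean supplied by the data producer —
the underlying rule operates on observer fields of view that we do not
model, so the flag is part of the input contract, and the synthetic
generator emits it). Filtering is idempotent and sightings are dropped
with their segments.

Perpendicular distances come either directly from the survey software or
from inclinometer declination angles via `x = h / tan(θ)` at the 234 m
survey altitude; 90° maps to exactly 0. Distances are kept in meters
throughout and converted to kilometers only inside the estimator, which
avoids silent factor-of-1000 errors when mixing meter distances with
kilometer effort. Dates are ISO-8601 and times stay local (a single time
zone covers the study area). Sightings without a group size are rejected
rather than imputed, because the group-size estimator needs them.

# Detection function

The detection model is `g(x) = key(x) · series(x)`, renormalized so
`g(0) = 1`, with the conditional likelihood
`f_i(x) = g_i(x) / ∫₀ʷ g_i(u) du` maximized over the observed distances.
Keys are half-normal `exp(−x²/2σ²)` and hazard-rate `1 − exp(−(x/σ)^−b)`
(shape parameterized `b = 1 + exp(θ)`). Series adjustments follow the
conventional pairings — cosine with either key (orders 2, 3 of
`cos(jπx/w)`), Hermite polynomials `H4, H6` of `x/σ` with the half-normal
only, simple polynomials `(x/w)⁴, (x/w)⁶` with the hazard-rate only — and
the number of terms (0–2) competes by AIC along with the key, since the
adjustment order is a free modelling choice. Any adjusted fit whose
detection function is negative or non-monotone anywhere on a 1,000-point
grid per covariate class is rejected, the standard shape constraint for
distance sampling.

Beaufort sea state enters as a categorical covariate on `log σ` with the
lowest observed level as reference — the usual way a discrete
sighting-condition covariate enters multiple-covariate distance sampling.
With no covariates the same code path *is* conventional distance
sampling, and a test asserts the log-likelihoods agree to 1e-6. For
covariate models `f(0)` is the sightings-average of `1/μ_i`, where `μ_i`
is the effective strip width for sighting `i`'s covariate class.

Numerics: the strip-width integral uses adaptive quadrature
(`stats::integrate`, relative tolerance 1e-10, evaluated once per
covariate class per likelihood call); optimization is BFGS from three
starting points (`log σ₀` at `log √mean(x²)` and ±0.7) with relative
tolerance 1e-12; the parameter covariance is the inverse observed
information from a numerical Hessian, and `se(f0)` follows by the delta
method with central-difference gradients. A brute-force quadrature oracle
in the test suite reproduces the likelihood to 1e-8 on small datasets.

Truncation is a user choice with two strategies: the 95th percentile of
distances (type-7 linear interpolation; the default) or the distance at
which a pilot half-normal fit falls to `g(w) = 0.15`,
`w = σ̂ √(−2 ln 0.15)`. Both are provided because the appropriate
truncation depends on the tail behaviour of each dataset.

**Group size.** Larger groups are seen farther out, so the sample mean
overestimates `E(s)`. We regress `log s` on the fitted `ĝ(x_i)` and
predict at `ĝ = 1` with the half-variance lognormal back-transform, but
only when the slope is significant at α = 0.15 (the conventional gate for
size-bias regression); otherwise the arithmetic mean and its standard
error are used. Degenerate regressors (all distances equal) fall back to
the mean with a warning, and the estimate is floored at 1 because groups
have at least one member. The regression SE ignores the (small)
uncertainty of the residual-variance term.

# Encounter-rate variance

Systematic parallel lines leave no design-based replicate, so `var(n)`
uses the overlapping post-stratification ("O2") successive-difference
family of Fewster et al. (2009): adjacent lines, in the geographic order
given by the effort file (the documented ordering contract), form
overlapping pairs, and

```
var(n) = k/(k−1) · Σⱼ [ l²ⱼ₋₁ (rⱼ₋₁ − r̄ⱼ)² + l²ⱼ (rⱼ − r̄ⱼ)² ]
```

with `r_j = n_j / l_j` and `r̄_j` the pair's pooled rate. The
length-squared weights make the estimator unbiased for independent
Poisson counts (verified by simulation against replicate variance), while
the successive-difference structure absorbs smooth spatial trends. A
single line falls back to Poisson `var(n) = n` with a warning.

# Availability from tags

**Event definitions.** A minute is dry when the wet/dry sensor recorded
at least 30 s dry; a haul-out state opens once five consecutive dry
minutes accrue and closes at the first minute with at most 15 s dry (wet
≥ 45 s) or at any recording gap. The onset is backfilled to the start of
the qualifying dry run: opening the state only after the fifth minute
would systematically shave five minutes off every haul-out event, and the
five-minute requirement is a debounce, not part of the event. Minutes
with 16–29 dry seconds neither extend a run nor close a state. Dives
shallower than 3 m or shorter than 20 s are ignored when raw event lists
are supplied (the tags open and close dives at 1.5 m); hourly dive
minutes from the tag firmware are used as-is.

**Weekly binning.** Weeks are fixed seven-day day-of-year bins (January
1–7 is week 1), and weeks in which fewer than five distinct seals report
are dropped entirely to avoid a handful of animals dominating the
seasonal pattern. The retained animal-week pairs are the "seal periods"
reported with each correction factor; the original tables count
"seal-biweeks" under a duty-cycle convention that is not recoverable, so
animal-weeks are reported instead and documented as such.

**GLMMs.** Both processes are modelled on the logit scale with hour of
day and week of year as fixed factors shared across animals, plus random
intercepts for animal and animal-by-week, fitted by maximum likelihood
with the Laplace approximation in glmmTMB. The haul-out response is
binomial; wet/dry minutes are collapsed to one Bernoulli trial per
animal-date-hour (an hour counts as hauled out when most of its minutes
were dry) because minutes within an hour are almost perfectly dependent —
treating them as independent trials would understate every standard
error. The dive response is the fraction of each hour in a dive state
under a Beta family with precision φ, squeezed off the boundary with
`y' = (y(n−1) + 0.5)/n`, `n` the number of hourly observations in the
fit — the standard transform for Beta regression on [0, 1] data.

**Prediction and correction factors.** Predictions are for an average
untagged seal: random effects at zero, fixed-effect uncertainty
propagated by drawing 10,000 multivariate-normal samples in link space
(seeded; the seed is recorded in the output), inverse-logit transforming,
and combining per draw as `avail = (1 − h)(1 − d)`. Haul-out and dive
probabilities are combined under independence because the two sensors do
not log continuously enough to model them jointly; this is an assumption,
not an estimate. Cells outside the fitted weeks are returned as missing
rather than extrapolated. The seasonal availability is the unweighted
mean of cell means over the season's date-hour cells in the 0900–1700
survey window (no effort weighting is attempted because none is defined
for the tag data), the factor is its reciprocal, and its SE is the
standard deviation of the per-draw seasonal means. Winter has no tag
data, so requesting a winter factor is an error and winter estimates stay
uncorrected end-to-end. Tidal covariates are deliberately absent from the
model: they were considered and rejected upstream on predictive grounds,
and the synthetic generator does not simulate tides.

# Aggregation conventions

Corrected abundance is exactly the uncorrected abundance times the
factor; the availability CV joins the others in quadrature. Pooling
strata (the two northern survey strata form the Washington Northern
Inland Waters stock) adds abundances and areas and combines variances
under independence, `CV = √(Σ (cvᵢNᵢ)²) / ΣNᵢ`. Year-round rows are an
*averaging convention, not a variance law*: abundance, density, CV and
both interval bounds are each the arithmetic mean of the seasonal values —
this is the rule that reproduces published year-round rows exactly, and
it is documented as a convention. The published pooled uncorrected CV for
the northern stock is not reproducible from its components by any simple
rule (mean, weighted mean, or quadrature); the delta-method rule above is
used as the statistically standard choice. Report rounding (abundances to
integers, densities and CVs to two decimals) happens only at the report
layer.

# The synthetic generator

`simulate_survey()` places groups by a homogeneous Poisson process per
stratum-season with intensity `density × availability / E(s)` — seals
ashore or on a dive are simply never placed, which matches the
instantaneous-availability assumption of the estimator — and samples them
with systematic parallel lines at the design spacings (3.7 km, 1.8 km in
Hood Canal, wider in the northern waters) with a uniform random start.
Geometry is one-dimensional per stratum (line positions along one axis,
group offsets perpendicular); there are no coastlines or GPS tracks.
Detection is half-normal with scale declining as Beaufort rises (230 m at
Beaufort 0 down to 170 m at Beaufort 2 — effective strip widths of a few
hundred meters, the scale typical of small-pinniped aerial surveys);
group sizes are zero-truncated Poisson (λ = 0.6, mostly singletons);
default total densities are in the range the corrected seasonal estimates
report, with availability 0.429/0.373/0.249 for spring/summer/autumn.
Connector and transit segments, Beaufort 3+ segments and glare flags are
emitted so every filter rule is exercised.

`simulate_tags()` emulates the 2016 deployment: 15 adults (10 M / 5 F)
tagged over a four-week window, transmitting daily from April 15 to July
31 and every sixth day otherwise, weeks 14–40. Haul-out and dive
probabilities are logit-linear with a cosine hour-of-day shape (trough at
13:00, so availability peaks at midday), a linear week ramp rising toward
the autumn molt, and animal (SD 0.6) and animal-by-week (SD 0.4) random
effects — heterogeneity magnitudes typical of pinniped telemetry. Hourly
haul-out states generate minute streams that are fully dry inside
intervals and fully wet outside, with boundary minutes of 45 and 10 dry
seconds exercising the 30 s / 45 s thresholds while keeping the interval →
minutes → state-machine round trip exact. Dive minutes are Beta draws
(φ = 15) *independent of the haul-out state*, mirroring the independence
assumption of the availability model; winter weeks are not generated by
default, mirroring the missing winter factor.

What the generator does **not** emulate — tides, weather persistence,
spatial clustering of seals near haul-outs, observer perception error,
non-instantaneous cue production, age/sex structure in the tagged sample —
bounds what passing tests can show: they demonstrate that the estimators
recover the truth of this generating model, not that the model captures
every feature of real survey data.

# Verification studies and problem sizes

Three seeded studies back the acceptance checks (shared by
`scripts/acceptance.R`): `detection_recovery_study()` refits 5,000
truncated half-normal distances (σ = 200 m, w = 500 m) and a 4,000-sighting
Beaufort-covariate design where σ doubles from Beaufort 0 to 2;
`availability_recovery_study()` runs the full tag chain at 15 animals ×
20 weeks and compares the seasonal factor to the generating truth over the
same weeks the estimate used; `calibration_study()` runs 200 replicate
single-stratum surveys (≈85 sightings each) through the whole estimation
chain, using the generating availability (with a nominal SE) as the
correction so that the study isolates the survey estimator's calibration —
the tag chain has its own recovery study, and mixing the two errors would
make neither interpretable. These sizes give Monte-Carlo standard errors
comfortably below the tolerances being checked while completing in a few
minutes on one core.

# Known limitations

Perception bias is uncorrected by design: the correction accounts only
for availability, and estimates inherit any failure of the
belly-window-covers-the-trackline assumption. The tagged sample is 15
adults skewed male, spring/summer-heavy, with no winter data; the
correction factors assume each season's tag data represent that season.
Stratum areas are configuration inputs, not estimated quantities, so
densities are only as good as the configured areas. The independence of
haul-out and dive processes is assumed, not tested. Year-round rows use
the arithmetic-mean convention described above and should not be read as
variance-weighted syntheses.
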