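---
title: "Methods: residence metrics, presence modelling and catch-rate standardization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residence metrics, presence modelling and catch-rate standardization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spawnsite)
```

This vignette documents the models, conventions and design decisions
behind the package: what each arm assumes, which parameters matter, what
the synthetic generators do and do not emulate, and where genuinely open
choices were resolved.

## Time and dates

All timestamps are fixed-offset Eastern Standard Time (UTC−5)
year-round, with no daylight-saving transitions. Hour bins are
clock-aligned and half-open, `[HH:00, HH+1:00)`. Both conventions exist
for reproducibility: a DST-aware timezone would shift bin boundaries
mid-season, and bin alignment is otherwise arbitrary. Dates in fixtures
are ISO-8601; `M/D/YYYY` is accepted on input. Coordinates are planar
meters (UTM-like); no geodesy is implemented or needed at the sub-2-km
scale of a receiver array.

## Telemetry processing

**Spurious filter.** A detection is discarded when it is the only
core-array detection of its transmitter in a 24 h period; isolated
pings at this rate are more plausibly code collisions than fish. The
"24 h period" is implemented as the local calendar day (a rolling
24 h window is available via `window = "rolling"`). The calendar-day
reading matches the daily granularity of every downstream metric and
makes the filter a pure group-and-count, which the tests verify against
a brute-force oracle.

**Post-release window and censoring.** The first 48 h after
implantation are set aside (handling stress), with the boundary
half-open: a detection at exactly +48 h belongs to the study period.
Tags that die or are lost are censored after a recorded date;
`flag_stationary()` proposes censor dates by scanning for runs of
`min_days` consecutive days confined to a receiver-number range of at
most `receiver_spread` — it assists, but does not replace, the manual
mortality call.

**Positions.** The weighted-means estimator places a tag-hour at the
detection-count-weighted centroid of the receivers that heard it.
Weights are non-negative, so positions always lie in the convex hull of
contributing receivers and are translation-equivariant (both are tested
properties). The weighted mean receiver number is carried as a second
location measure; for a linear array it is a serviceable 1-D coordinate
and it reproduces the expected behavior of a mid-channel reference tag
placed between receivers 9 and 10 (long-run mean in 9.5–10.5).

**Zones.** Zone geometry is a configuration artifact (polygons plus a
receiver→zone lookup), because in the field zones are drawn by hand
around bathymetry. The default synthetic geometry places zones 1–6 along
the channel (gulf → inner estuary) and zone 7 as a northern refuge; the
core array (receivers 3–19) covers zones 2–3, the spawning site.
Containment uses even-odd ray casting; points outside every polygon or
on shared boundaries resolve deterministically to the nearest polygon
centroid. The test oracle is an independent winding-number routine.

**Control-tag audit.** The audited error is the easting error, the
axis along which this channel array discriminates; the Euclidean error
is also reported. The detection rate divides distinct received
transmissions by the count expected from the fixed 60 s delay over the
monitoring period.

## Residence metrics

`TP` counts both endpoints (`last − first + 1`). The convention is not
stated in most field reports; this choice reproduces every printed
value in the packaged fixture (e.g. 6/4→8/19 gives 77 d; 3/21→9/20
gives 184 d), which is the strongest available evidence.

The residence index is restricted to fish detected on "enough" dates.
The summary's default eligibility is `DD ≥ 5`. For the correlation
between whole-array and spawning-site indices, however, a spawning-site
threshold of `DD_SS ≥ 4` is the default: with ≥ 5 the fixture yields 37
pairs, with ≥ 4 it yields the published pairing of 38. The package
honors the published n; the one-unit discrepancy is documented here
rather than resolved, and the threshold is an argument.

The relocation-proportion series divides fish detected per day by the
tags active that day — a tag counts toward the denominator only while
its annual duty window and battery horizon cover the date and it is not
censored. Without this, late-season proportions are biased once
single-season tags expire.

Two published statistics are deliberately not asserted anywhere: the
by-sex Mann-Whitney U of 454 exceeds the maximum possible (20×18 = 360)
for the eligible subset, so the grouping behind it cannot be
reconstructed; and the zone chi-square of 3186.8 (df 3) is not
reproducible under equal expected proportions, suggesting
receiver-count-based expectations that are unstated. Both statistics
are computed (both U orientations; user-suppliable expected
proportions) but left uncompared.

## The presence model

Records are fish-days: one 0/1 outcome per active, uncensored tag per
spawning-season date (April–September), with `present = 1` iff at least
one hourly position fell in zones 2–3 with bin start in `[14:00,
20:00)`. Fish-hour granularity is available but the daily coding is the
default — the diel window is short enough that within-day replication
adds mostly autocorrelation, not information.

The fit is a penalized binomial likelihood with cyclic cubic regression
splines for day of year (period 365.25, so multi-year phases stay
aligned; basis dimension 10) and lunar phase (period 360; basis
dimension 8), a sex contrast, sex-specific linear size slopes (total
length centered within sex, entering separately per sex because of the
protandric life history), and a per-fish random intercept in its ridge
representation. Smoothing parameters and the random-intercept variance
are selected by REML via `mgcv::gam`; term p-values are the approximate
Wald tests of the mgcv summary. Basis dimensions are implementation
choices — alternative spline bases had minimal effect, consistent with
the source analysis. Lunar phase is the mean-synodic approximation
(29.530588853 d from the 2000-01-06 18:14 UTC new moon), accurate to a
few degrees across 1990–2050, which is ample for an effect with ≈ 50°
of intrinsic width.

Complete separation (a sex with all-zero outcomes) is flagged but the
penalized fit is still returned, as the smoothing penalties keep it
finite. Population-level predictions exclude the random-effect column.

## Synthetic generators

**Telemetry.** Daily presence truth follows the same logistic model the
estimator assumes: baseline −1.0, sex effect +1.0 (M−F), seasonal
amplitude 1.5 peaking on day 182, semi-lunar amplitude 0.8 (a
`cos(2θ)` term peaking at both new and full moon), per-fish intercepts
with SD 0.8 — prevalences around 0.3–0.5, matching a site where most
fish appear on a minority of season days. Present fish occupy a few
hourly bins at the spawning site inside 1400–2000 h and a few refuge
bins (receiver 23 area) at other hours; this two-state track is the
minimum structure that produces realistic site/refuge movement paths,
and is a stand-in — real within-day movement rates are not quantified.
Ping emission uses the tag's mean inter-ping delay; each ping is
detected independently per receiver with a logistic distance kernel
calibrated to 50% at 85 m (the long-term range-tested value); the slope
(0.05 m⁻¹) is a free parameter since only the 50% point is established.
Detection counts per bin-receiver are drawn binomially, which is
exactly the ping-level process marginally; control tags are simulated
ping by ping so that one transmission shares a timestamp across
receivers and distinct-transmission detection rates are meaningful.
Each fish consumes its own RNG stream split from the master seed, so
enlarging the simulated cohort never perturbs existing fish. What the
generator does **not** emulate: tidal modulation of detection range,
transmitter collisions, or 3-D structure — passing tests say nothing
about those.

**Survey.** Hauls are laid on a near-square lattice of one-nautical-mile
grids, monthly, with presence Bernoulli on the logit scale (intercept
−1.4; year, region +1.2, spawning season +0.8, temperature-bin 0.15 per
bin) and positive catch lognormal (meanlog 1.0 plus year, region +0.6,
vegetation +0.4; sdlog 0.8) rounded and forced ≥ 1. Two catch hotspots
define the true concentrated region (radius 2.2 grid widths).
Temperature follows an annual sinusoid, salinity a west-east gradient,
vegetation is a per-grid property — enough correlation structure to make
covariate selection non-trivial, but no spatial autocorrelation in the
residuals, no vessel or gear effects.

## Catch-rate standardization

The KDE is a CPUE-weighted product-Gaussian evaluated at surveyed grid
centers, with an edge correction (dividing by the kernel mass inside the
survey extent) so boundary grids are not spuriously down-weighted.
Bandwidth defaults to two grid widths and the contour to 50% of density
mass; both are unstated in the source analysis, are exposed in the
output metadata, and can be set per run. Whether the source KDE was
CPUE-weighted or positives-only is also unstated; weighted is the
default, `weighted = FALSE` gives the alternative.

Forward selection starts from the year-only model (year is forced, it
carries the index) and greedily adds the candidate most reducing AIC
until no addition reduces it — so the final AIC is never above any
single-term augmentation, a tested invariant. Month and spawning season
are aliased descriptions of the same calendar; whichever enters first
blocks the other. The region×season interaction is offered only once
both parents are in. Temperature and salinity bins holding fewer than
`min_bin_n = 10` hauls are pooled into their neighbor before fitting —
near-empty factor cells otherwise make marginal means unestimable.

Marginal means average over a balanced grid of the other factors (equal
weight per level, via emmeans); the reference grid of the source
analysis is unstated and balanced averaging is the assumption. The
Monte-Carlo combination draws Student-t realizations per year around
each sub-model's marginal mean with the sub-model's residual df (capped
at 200, effectively normal), back-transforms — inverse logit, and
`exp(μ + σ²/2)` with the lognormal half-variance correction (toggleable
to naive `exp`) — and multiplies. Draws are seed-reproducible bit for
bit.

## Problem sizes used by the checks

The simulation-based checks run at sizes chosen to make the recovery
targets statistically meaningful while staying desk-scale: presence
model at 40 fish × 150 days × 20 seeds through the full acoustic
pipeline, null-lunar calibration at 50 model-level replicates, hurdle
selection/ranking at 100 grids × 6 years × 24 hauls/month × 20 seeds,
and the hurdle-decomposition conservation check at ≈ 50,000 hauls.

## Known limitations

- The spurious filter's calendar-day reading removes a true singleton
  at 23:59 whose pair arrives at 00:01; the rolling window handles
  this, at the cost of a less transparent definition.
- The weighted-means position is biased toward receiver-dense parts of
  the array; the audit quantifies but does not correct this.
- Under a strict forward-AIC rule, 1-df covariates with no effect still
  enter a sub-model with probability ≈ 0.16 each (the AIC penalty of 2
  versus a χ²₁ improvement); with several null candidates the all-null
  final model is retained only about half the time. This is a property
  of AIC selection itself, not of the implementation; analysts wanting
  conservative selection should use fewer candidates or a stricter
  entry rule.
- The lunar covariate is the mean-synodic phase, not an ephemeris;
  errors of a few degrees are irrelevant here but would matter for
  eclipse-grade work.
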