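# spawnsite

Tools for analyzing spawning-site fidelity of estuarine fish from two
complementary data streams: passive acoustic telemetry at an inlet
spawning site, and a long-running fishery-independent haul-seine survey
of the surrounding estuary. The package was built around a study of
Common Snook spawning at an inlet at the mouth of a large Gulf-coast
estuary, but every step is generic: it applies to any site monitored by
a fixed receiver array and any zero-inflated catch-rate survey.

## What it computes

**Telemetry arm.** Raw detections (one row per received transmitter
ping) are filtered (a single core-array detection from a tag within a
24 h period is treated as spurious), split into post-release (first
48 h) and study periods, censored after suspected mortality, and
collapsed into hourly positions by the weighted-means method: the
position for a tag-hour is the detection-count-weighted mean of the
coordinates of the receivers that heard it, with the weighted mean
receiver number as a second, one-dimensional location measure.
Positions are assigned to detection zones; zones 2–3 form the spawning
site. From the zone-labelled positions the package derives, per fish
and year and for each spatial scope (whole array / spawning site):

- `DD` — number of distinct dates detected,
- `TP` — total period, the inclusive span from first to last detection
  (`last − first + 1` days),
- `RI = 100·DD/TP` — the residence index (percent).

Daily presence at the spawning site within the diel spawning window
(1400–2000 h) is then modelled with a binomial additive mixed model
(logit link):

```
logit P(present_ij) = sex_i + f_doy(doy_j) + f_lunar(lunar_j)
                      + size_i·[sex] + b_i,   b_i ~ N(0, σ²)
```

where `f_doy` and `f_lunar` are cyclic cubic regression splines
(periods 365.25 d and 360°), lunar phase is continuous 0–360 with new
moon at 0/360 and full moon at 180, and `b_i` is a per-fish random
intercept. Smoothing parameters and the random-effect variance are
selected by REML (mgcv).

**Survey arm.** Haul-seine catch rates of adults are standardized with
a delta-lognormal hurdle model: survey grids are first classified into
concentrated / not-concentrated regions by a CPUE-weighted 2-D Gaussian
kernel density estimate; then two sub-models — binomial presence and
lognormal positive catch — are selected by forward-AIC from candidates
{year (forced), month, region, season, region×season, 2.5°C temperature
bins, 2.5‰ salinity bins, vegetation}; finally, year-specific marginal
means from the two sub-models are combined by Monte Carlo (10,000
Student-t draws each, inverse-logit and `exp(μ + σ²/2)`
back-transforms, multiplied) into annual index distributions.

A synthetic-data module generates both streams with known ground truth
(42-receiver array, range-dependent detection with 50% probability at
85 m, tag duty cycles, stratified survey with catch hotspots), so the
whole pipeline is testable against truth.

## Worked example

The packaged fixture reproduces the published per-fish-year summary of
the 30 tagged fish (46 fish-years). Recomputing the residence metrics
from its raw ingredients:

```r
library(spawnsite)
t1 <- load_table1_fixture()
r  <- residence_index(dd = 43, first_date = as.Date("2007-06-04"),
                      last_date = as.Date("2007-08-19"))
r
#>   tp       ri
#> 1 77 55.84416
mean(t1$tp_a[t1$year == 2007])          # mean 2007 residence time (d)
#> [1] 65
rc <- ri_correlation(table1_to_residences())
c(r = rc$r, n = rc$n)
#>          r          n
#>  0.9058444 38.0000000
```

A fish detected on 43 distinct dates over an inclusive 77-day span has
a whole-array residence index of 55.8%; the mean 2007 total period
across the 30 fish-years is 65 days; and the whole-array and
spawning-site residence indices correlate at r ≈ 0.91 over the 38
eligible pairs — fish that frequent the array are the same fish that
frequent the spawning site.

The full synthetic pipeline is driven by the numbered scripts:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_process_telemetry.R
Rscript analysis/03_residence.R
Rscript analysis/04_presence_model.R
Rscript analysis/05_cpue_index.R
```

Each stage prints what it found (record counts through every filter,
control-tag position error, the fitted sex contrast and smooth shapes,
the selected hurdle terms and the annual index) and writes its tables
under `results/`.

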