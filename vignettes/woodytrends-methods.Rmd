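---
title: "Methods: hexagon-grid woody vegetation trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hexagon-grid woody vegetation trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodytrends)
```

# The model and its assumptions

`woodytrends` detects long-term directional change in woody vegetation
cover (trees plus shrubs) by aggregating annual 250 m land-cover maps into
hexagonal analysis cells and testing each cell's 14-year woody-area series
for a linear trend.

The statistical core is deliberately simple. For hexagon $h$ with annual
woody area $A_h(t)$ (hectares, $t$ = calendar year 2001..2014),

$$A_h(t) = \beta_{0h} + \beta_{1h} t + \varepsilon_{ht},
  \qquad \varepsilon_{ht} \sim \mathrm{iid}\; (0, \sigma_h^2),$$

fitted by ordinary least squares. The two-sided $t$ test on
$\hat\beta_{1h}$ (df = 12) at $\alpha = 0.05$ filters hexagons into gain
($p < \alpha$, slope > 0), loss ($p < \alpha$, slope < 0) or no-trend. The
method's premise is that pixel-level year-to-year misclassification behaves
like serially independent noise at the ~1,850-pixel hexagon scale, so a
significant slope indicates sustained directional change rather than
flicker. Assumptions worth keeping in mind:

* errors are treated as independent across years — a strong drought
  spanning several seasons violates this and inflates false positives;
* the trend is assumed linear; abrupt single-year conversions are detected
  with reduced power and breakpoint models are out of scope;
* each hexagon is tested at $\alpha$ with no multiple-testing correction
  across cells, reproducing the original analysis. The false-positive
  *count* therefore scales with the number of cells;
  `classify_hexagons(..., adjust = "BH")` provides a Benjamini–Hochberg
  sensitivity switch (off by default).

Net change is the observed endpoint difference $A_h(2014) - A_h(2001)$, not
$13 \hat\beta_{1h}$: the reported quantity is "how much woody area this
cell ended up with", and the endpoint form makes the per-zone accounting an
exact identity (zone net = zone loss + zone gain; grand net = sum of
significant-hexagon nets). The fitted-endpoint variant is available via
`fit_trend(..., net = "fitted")`.

A note on the significance convention: the source material prints the
filter once as "p > 0.05" and once as "(p < 0.05)"; the package implements
$p < \alpha$ = significant, treating the former as a typographical slip —
the opposite reading would keep the *noise* cells and discard the trends.

# Geometry

Cells are regular hexagons with flat sides facing north and south, so the
north–south extent equals the flat-to-flat width $w$; area is
$(\sqrt3/2)w^2$, and $w = 11.547$ km gives the study's 115.47 km²
(~11,547 ha) cells. The printed "11 km north to south" is taken as a
rounding of 11.547: only that width reproduces the printed area, and every
downstream number depends on areas, not on cell positions. Whether the
original grid was flat-top or pointy-top is not recoverable; orientation
only relabels cells, and all tests are orientation-invariant.

A hexagonal tiling is the Voronoi diagram of its centers, so pixel
membership (by pixel center) is computed as nearest-center assignment;
centers exactly on a boundary resolve deterministically to the smallest
cell id. Pixel area is fixed at 6.25 ha — the synthetic world is a planar
equal-area coordinate system in meters, which preserves the area accounting
while avoiding projection machinery.

Elevation zones are seven half-open 500 m bins, $[1{,}000, 1{,}500)$
through $[3{,}500, 4{,}000)$ plus $[4{,}000, \infty)$, matching the printed
labels; the threshold "median elevation ≥ 1,000 m" is inclusive. Hexagon
elevation is the median over DEM cells whose centers fall inside; country
membership is by majority cell count; biome membership by any
intersection.

# Features and classification

Per pixel-year, observations with reliability code 3 are removed, then five
statistics (mean, sample SD with $n-1$ denominator, min, max, range) are
computed per variable over six windows. The window description "all 12
months, two 6 month periods, three 4 month periods" admits two readings;
the default (`window_mode = "six"`) uses one 12-month window (150 features),
the alternative (`"seventeen"`) uses 12 calendar-month windows plus halves
and thirds. Window boundaries are by composite start day-of-year: halves
1–182 / 183–365; thirds 1–121 / 122–243 / 244–365. The 23rd composite is
short (365/16 ≈ 22.8), matching the product convention.

Degenerate inputs have documented conventions rather than silent zeros: an
empty window yields missing statistics; a one-observation window yields a
missing SD; a fully-dropped sub-annual window is imputed with the annual
statistic; a pixel-year whose annual window is unusable is excluded from
training and classified "other" (flagged as nodata-derived).

Classification is a stock Random Forest (`ranger`, 500 trees by default,
seeded, single-threaded for determinism) per mapping zone, zones following
the biome delineations. Training samples pair with the features of their
reference year only. Plantation is *not* woody in the default binarization:
the analysis targets natural woody cover, and plantation expansion is one
of the known contaminants of apparent forest gain; a config switch includes
it for sensitivity analysis.

# Driver analysis

For significant hexagons, outcome gain = 1 / loss = 0 is regressed on
country, elevation class (the 7-level categorical), mean Horn slope
(degrees; Horn's 3×3 method with edge replication, the standard GIS
default), ΔNTL and Δ rural population (municipality values allocated to
hexagons by overlap-area weights, which conserves municipality totals).
All $2^5 = 32$ main-effect subsets are fitted by maximum likelihood;
$\mathrm{AIC} = -2\log L + 2k$, and Akaike weights are normalized over the
*full* candidate set — the printed four best-model weights sum to ~0.70,
which is only consistent with full-set normalization. Perfectly separated
fits are flagged and excluded from the ranking with a warning. Reference
levels for categorical terms are the first level (alphabetical for
country, lowest zone for elevation).

# What the synthetic generator emulates — and what it does not

`generate_landscape()` produces a fully truth-labeled world: a DEM (south
to north elevation ramp 800–4,200 m plus smooth relief, SD 150 m),
elevation-banded biomes, discrete-Voronoi countries and municipalities,
per-class seasonal composite signals (sinusoid plus Gaussian noise, second
harmonic for cropland's double cropping; levels chosen so woody cover has
high stable EVI and low MIR, bare "other" the reverse), persistent
per-pixel level jitter (SD 0.02 EVI), independent reliability dropouts
(default 5%), and scripted class transitions converting a fixed fraction of
a region's initial from-class pixels per year — which makes the true
hexagon woody series linear in year within one pixel of rounding, the
property the trend filter is designed to detect. Municipality population
change is a Gaussian null (SD 50 persons) minus 2 persons per hectare of
scripted abandonment, so depopulation and regrowth are linked with known
sign.

Two calibration simulators bypass the pixel stage where it adds nothing:

* `simulate_hexagon_series()` models the observed woody count as
  $\mathrm{Bin}(n_{\mathrm{woody}}, 1-e) + \mathrm{Bin}(n - n_{\mathrm{woody}}, e)$
  per year. The transient error rate defaults to $e = 0.02$: the real
  analysis reported ~94% binary accuracy, but most of that 6% error is
  persistent per pixel (the same confusable land cover is misread every
  year) and persistent error shifts a series' level without perturbing its
  slope; only the transient component adds trend noise, and one third of
  the total is a defensible split. At hexagon scale this gives a
  year-to-year SD of ~38 ha, against which a scripted conversion of
  2 pixels/yr (12.5 ha/yr) is detectable with high power.
* `simulate_driver_records()` draws gain/loss outcomes from known logit
  coefficients (loss dominating below 1,500 m, gain above, modest country
  contrasts, −0.004 per person of rural population change, zero effects for
  slope and NTL) for parameter-recovery and model-selection checks.

What the generator does **not** emulate: spatially correlated cloud cover
(dropouts are independent), radiative-transfer realism, mixed pixels at
class boundaries, temporally persistent classification confusions, the
sinusoidal-projection variation of real pixel areas, and real class
imbalance (>60,000 hand-labeled samples vs the synthetic stratified draw).
Passing tests therefore demonstrate that the *machinery* is correct and
calibrated under the stated noise model — not that real-data accuracy would
reach the synthetic world's near-perfect separability.

# Numerical choices and problem sizes

* OLS is fitted via `stats::lm`; tests verify slope and p against an
  independent closed-form normal-equations oracle to 10⁻¹⁰ relative.
* Zero-variance series (e.g. an all-rock hexagon with 14 zeros) return
  slope 0, p = NA, direction "none" rather than erroring.
* Boundary pixel centers tie-break to the smallest hexagon id; the
  containment tolerance is 10⁻⁷ of a squared width.
* Stage seeds are derived deterministically from one master seed;
  `ranger` runs single-threaded so reruns are bit-identical.
* The test and example worlds are scaled for quick iteration: 40 × 40
  pixels with 2.5 km hexagons for pipeline tests, a 100 × 100-pixel world
  with the real 11.547 km geometry for the classifier check, 2,000
  simulated hexagons for trend-filter calibration, and 1,000 records for
  driver recovery. These sizes give the calibration checks binomial
  standard errors tight enough to be informative (e.g. ±1.5 percentage
  points on the null significant fraction at $n = 2{,}000$).

# Known limitations

* No temporal smoothing or post-classification filtering between annual
  maps; the trend filter is the only temporal regularizer.
* No spatial autocorrelation handling in either the trend tests or the
  logistic models; neighboring hexagons share weather and markets, so
  effective sample sizes are smaller than nominal.
* Mann–Kendall / breakpoint alternatives and interaction terms in the
  driver models are listed as future work, not implemented.
* Vector layers are planar polygons in a synthetic equal-area world;
  ingesting real projected rasters is a separate concern handled upstream
  of this package.
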