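---
title: "Interpolating freshwater calcium and pH: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating freshwater calcium and pH: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(aquainterp)
```

## The problem

Freshwater calcium concentration and pH shape chemistry and biology across
lakes and rivers — acidification sensitivity, contaminant toxicity, and the
invasion risk of calcium-limited organisms such as dreissenid mussels all
depend on them. Direct measurements exist only at monitoring sites, are
collected by many agencies under inconsistent conventions, and are absent
over large regions. This package turns such heterogeneous point records
into continuous raster surfaces by spatial interpolation, together with an
honest account of which interpolator to trust and how uncertain the
surface is.

The workflow has five stages: record-level quality control, aggregation to
one robust value per site, variogram estimation, interpolation, and
cross-validated method comparison. Each stage is an exported function; a
single call to `run_pipeline()` composes them.

## Quality control and harmonization

Compiled water-quality tables mix units, fraction labels, detection-limit
conventions, and the occasional non-freshwater record. The QC rules, in
the order applied by `qc_pipeline()`:

* **Keyword exclusion.** Records whose site name or type contains an
  exclusion keyword (e.g. `WASTEWATER`, `MARINE`) are dropped — they
  describe effluent or saline water, not ambient freshwater. The match is
  a case-insensitive substring test, so `Clearwater Lake` survives.
* **Year filter.** Records before a configurable minimum year (default
  2000) are dropped; the threshold can vary by source so data-sparse
  regions may keep older records.
* **Units.** Calcium is converted to mg/L from the common dialects
  (`ppm`, `µg/L`, `meq/L` via the Ca²⁺ equivalent weight 20.04 g/eq).
  Records with blank or unrecognized units are excluded rather than
  guessed at.
* **Fraction selection.** Where a sample reports several calcium
  fractions, dissolved is preferred; unlabelled records are treated as
  dissolved, since dropping them would gut the data and paired-sample
  comparisons (`compare_fractions()`) show the common fractions agree
  with dissolved almost one-to-one. Rarely seen fractions (filterable,
  fixed) are always dropped. Grouping is by (site, date) because sample
  identifiers are not consistently available across sources.
* **Plausibility bounds.** Calcium above 500 mg/L is implausible in
  ambient freshwater and excluded, except inside a configured
  clamp region — standing in for naturally calcium-rich evaporite river
  systems in Texas — where values are clamped to 500 to preserve spatial
  coverage. Values under 0.05 mg/L (a common detection limit) are set to
  0.05 when flagged below-detection or accompanied by a detection limit,
  and excluded otherwise. pH outside [2.5, 12.5] is excluded, bounds
  inclusive.

Every rule reports its count; `qc_report` enforces
`n_input = n_kept + sum(exclusions)`, and value modifications (clamping,
detection-limit substitution) never change the kept count.

## Aggregation

Duplicates and pseudo-duplicates (replicates, multi-depth casts, the same
record in two databases) are neutralized by taking the **median of all
records per site per date**, then summarizing each site across dates.
Interpolation uses the per-site median of the site-date medians — robust
to outliers and to uneven revisit intensity. Quantiles use R's default
linear-interpolation convention (type 7) throughout; the standard
deviation uses the n−1 denominator and is undefined for a single value.
`within_site_variability()` contrasts temporal spread at a site with
spatial spread across sites; when the median within-site IQR is several
times smaller than the across-site IQR, a single temporally aggregated
value per site is a defensible interpolation input.

Sites with conflicting coordinates (beyond 6 decimal degrees) raise an
error naming the site instead of being silently averaged.

## Projection and grid

All distances are planar Euclidean in the North America Albers Equal-Area
Conic system (ESRI:102008, GRS80 ellipsoid), implemented from the standard
ellipsoidal formulas with forward/inverse round-trip agreement below
10⁻⁶ degrees. An equal-area projection keeps a fixed cell size meaningful
across a continent; the trade-off is scale distortion away from the
standard parallels (20°N and 60°N) — distances are exact on the standard
parallels and stretched/compressed by up to ~6% midway between them,
which is immaterial relative to variogram ranges of hundreds of
kilometres. Map datum differences (NAD27/NAD83/WGS84) are ignored: they
amount to at most a few hundred metres against a 10-km cell.

The prediction grid (`grid_spec()`) defaults to 10 × 10 km cells with the
origin snapped to cell-size multiples so identical inputs always produce
identical grids. Masking uses centre-in-polygon membership (even-odd
rule), and never alters retained values.

## Variogram model

Spatial dependence is modelled with the Matérn family in Stein's
parameterization,

$$\gamma(h) = c_0\,\mathbf{1}[h>0] + c_1\left(1 - \frac{2^{1-\kappa}}{\Gamma(\kappa)}
\left(\tfrac{2\sqrt{\kappa}h}{a}\right)^{\kappa}
K_\kappa\!\left(\tfrac{2\sqrt{\kappa}h}{a}\right)\right),$$

whose range parameter $a$ remains comparable as the smoothness $\kappa$
changes; $\kappa = 0.5$ is the exponential model with effective range
$a/\sqrt{2}$. The empirical variogram bins half squared differences into
15 equal-width bins up to one third of the maximum pair distance
(configurable); above 5,000 points a fixed-seed subsample of pairs bounds
memory. Fitting is weighted least squares with weights
$N_j/\gamma(h_j)^2$, re-evaluated iteratively, and $\kappa$ is chosen by
profile search over a fixed candidate set
$\{0.05, 0.1, 0.2, 0.3, 0.5, 1, 2, 5, 10\}$ rather than by gradient steps
— derivatives with respect to the Bessel order are ill-conditioned.

Two fits are produced: a free-nugget fit and a **zero-nugget** fit. The
nugget is micro-scale variance plus measurement error; forcing it to zero
makes kriging honour the data exactly, which suits variables whose site
medians are already noise-suppressed by aggregation. Which variant
predicts better is an empirical question settled by cross-validation, not
by assumption.

```{r variogram-example}
truth <- simulate_gaussian_field(variogram_model(0, 1, 1.5e5, 0.5),
                                 300, seed = 2)
ev <- empirical_variogram(truth$sites$x, truth$sites$y, truth$sites$z)
fit_variogram(ev, fix_nugget_zero = TRUE)
```

## Interpolators

* **Nearest neighbour (NN)** — the baseline; ties broken deterministically
  by site index.
* **Inverse distance weighting (IDW)** — weighted mean of the `nmax`
  nearest values with weights $d^{-idp}$; a coincident site is returned
  exactly. Rather than conventional parameter guesses, `optimize_idw()`
  searches the mixed space (integer `nmax` 1–30, continuous `idp`) for the
  pair minimizing RMSE or MAE under seeded 5-fold cross-validation, giving
  the RMSE-optimized (IDW-OR) and MAE-optimized (IDW-OM) variants.
* **Ordinary kriging (OK / OK-ZN)** — best linear unbiased prediction
  under an unknown constant mean, solved per target on the `nmax = 100`
  nearest sites with at least `nmin = 15` required (fewer yields a missing
  value, never a silent fallback). Kriging also returns the **kriging
  variance** — the only method here with a per-cell uncertainty — which
  grows with distance from data. No search-radius cap is applied: every
  target uses its `nmax` nearest sites regardless of distance.

Numerical choices: ill-conditioned kriging systems are retried once with a
diagonal jitter of $10^{-10}\times$ the sill (collocated-after-rounding
points must not abort a continental run); still-singular targets are
returned missing with a warning; round-off-negative variances are clamped
to zero.

## Cross-validation and method choice

`loocv()` drops each site in turn and predicts it from the rest;
`kfold_cv()` partitions sites under a mandatory seed. The variogram is
fitted **once** on the full data and reused across folds — deleting one
site of tens of thousands cannot materially move a binned variogram, and
refitting per fold would multiply cost for no benefit. Five metrics
summarize the held-out pairs (`error_metrics()`): Pearson *r*, RMSE, MAE,
mean bias error (MBE; positive = over-prediction), and median symmetric
accuracy $\mathrm{MSA} = \exp(\mathrm{median}|\ln(Z_i/Z'_i)|) - 1$, a
robust symmetric proportional error. `select_method()` ranks methods per
metric (bias by magnitude) and picks the winner of the four key metrics
{r, RMSE, MAE, MBE}; MSA is reported but secondary, being on a
proportional scale; ties are surfaced as joint-best.

```{r cv-example}
s <- truth$sites
model <- fit_variogram(ev, fix_nugget_zero = TRUE)
reports <- list(
  nn = summary(loocv(s, s$z, list(method = "nn"))),
  okzn = summary(loocv(s, s$z, list(method = "okzn", model = model,
                                    nmax = 50, nmin = 2))))
select_method(reports)$best
```

## The synthetic generator

`simulate_gaussian_field()` draws a Gaussian random field by dense
Cholesky factorization (exact, capped at 3,000 sites — the simplest
correct method at testing scale) with Matérn covariance plus nugget
noise. The default study conditions emulate the structure of continental
water-quality compilations:

* calcium-like fields are exponential transforms of a log-scale field
  (zero nugget, partial sill 0.8, range 200 km, $\kappa = 0.5$, mean
  log 3), spanning roughly 1–150 mg/L with a median near 20 mg/L and a
  long right tail;
* pH-like fields are Gaussian, centred at 7.9 with spatial standard
  deviation ~0.7;
* visits per site follow a geometric law with mean ~4 (right-skewed
  revisit intensity: most sites few dates, some hundreds), each visit
  carrying 1–3 replicate records; replicate noise is multiplicative
  lognormal for calcium and additive for pH.

`make_observation_table()` then plants known contamination — keyword
sites, over-limit values, censored values with and without flags, blank
units, out-of-range pH, paired dissolved/total fractions — and derives a
registry of expected per-rule counts **from the finished table**, so
values that land in a contamination class naturally are bookkept too.
Tests require QC counts to equal the registry exactly, per seed.

What the generator does *not* emulate: source-specific schemas, positional
errors and datum shifts, temporally autocorrelated revisits, or the
boundary geometry of real coastlines. Passing tests therefore demonstrate
correctness of the pipeline's logic and numerics, not that any particular
real-world compilation is clean.

## Problem sizes and tolerances

The test-suite simulations use 100–500 sites: large enough for stable
variogram estimation and for kriging to separate from baselines, small
enough that dense-matrix experiments run in seconds. Key numerical
contracts verified by the suite: zero-nugget kriging reproduces data to
1e−8 relative with variance below 1e−8 of the sill; local kriging with
`nmax ≥ n` matches a dense global solve to 1e−8; metrics match a naive
loop to 1e−12; the $\kappa = 0.5$ model matches the exponential closed
form to 1e−6; the fitted zero-nugget sill recovers a known generating
sill within 25% on average over 20 simulations.

## Known limitations

* A zero-nugget fit that profiles to a very smooth $\kappa$ (5–10) yields
  nearly singular kriging systems at small sample sizes; predictions can
  then degrade badly. This is a property of the model class, not a code
  defect — the cross-validated comparison exists precisely to catch it,
  and demotes the zero-nugget variant whenever it occurs.
* The variogram is stationary and isotropic; geological boundaries that
  produce sharp transitions are smoothed over, an error that shrinks with
  data density.
* Interpolation is univariate: no co-kriging against geology or other
  covariates, no machine-learning interpolators, no trend surfaces.
* The GeoTIFF support is deliberately minimal (single-band float64,
  uncompressed, little-endian, north-up) — exactly the files the package
  writes, readable by GDAL-based tools, but not a general TIFF reader.
* The Texas clamp region is a configurable bounding box standing in for
  the relevant river systems; users with exact basin geometry should
  supply it.
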