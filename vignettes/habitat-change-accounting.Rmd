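---
title: "Methods: from land-cover transitions to monarch habitat change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from land-cover transitions to monarch habitat change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatshift)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The estimation problem

Migratory monarch habitat quality in a region is approximated as a sum
over land-cover classes: each class $c$ covers an area $a_{c,t}$ (km²) at
date $t$ and carries a per-area resource value $v_c$ — a unitless 0–1
nectar or milkweed suitability index, or a milkweed density in plants/ha.
The resource total at date $t$ is

$$T_t = \sum_c a_{c,t}\, v_c\, u,$$

with $u$ a unit factor (100 ha/km² for densities, 1 for scores). Because
$v_c$ is uncertain — elicited from experts or fitted to sparse field
plots — it is treated as a random variable, and the change $T_1 - T_0$ is
estimated by Monte Carlo.

## Transition accounting

`compute_transition_matrix()` cross-tabulates paired class lattices into
an area matrix whose row sums are start-date class areas and column sums
end-date class areas. Cells with nodata at *either* date are excluded
from the tabulation entirely; keeping half-valid cells would break the
marginal identities that every downstream statistic relies on
(net = gain − loss = end − start, gross = gain + loss, and class nets
summing to zero over a closed extent). These identities are enforced as
exact (not approximate) expectations in the test suite, against a
brute-force cell-count oracle.

Annualization divides by an explicit `interval_years` rather than a
difference of year labels. The bundled Mexico table (2000–2020) is
annualized over 19 years because its published annual and percent-annual
columns are arithmetically consistent with that divisor, and the package
surfaces a warning whenever that convention is in effect; the Texas table
(2001–2019) uses the label difference, 18. Both accept any positive
divisor.

No reprojection or resampling is performed: grids must arrive aligned,
and geometry enters only through `cell_area`. Grids are plain integer
matrices; published or pre-tabulated per-class areas enter through the
CSV area-table path, which is how the bundled regional tables are driven.

## Resource-value distributions

**Survey scores.** Expert responses on the five-level scale (0.10, 0.25,
0.5, 0.75, 0.95) are aggregated per class × season × resource with the
sample mean and sample SD ($n-1$); cells with fewer than two respondents
are refused rather than silently given SD 0. Score distributions are
normal on the 0–1 scale.

**Scheme crosswalks.** When scores are elicited on one classification
scheme (e.g. a 14-class national vegetation generalization) but change is
measured on another (e.g. 8 satellite-derived strata), each target class
is a mosaic of source classes in the proportions of an agreement matrix
whose rows lie on the simplex. The default translation takes the
proportion-weighted average of both the source means *and the source
SDs*. Averaging SDs is not variance-correct for a mixture; it is retained
as the default because it is the convention under which the bundled
score tables were produced, and a `pooling = "variance"` mode (mixture
second moments) is available for comparison. The weighted-SD rule is
conservative in neither direction a priori; on separated means the
variance mode is strictly larger.

**Crop weighting.** A single generic cropland class receives the
share-weighted average of per-crop published floral values, after
dropping categories whose acreage cannot be cleanly attributed (grass/
sod) and renormalizing the remaining shares to one.

**Milkweed plot fits.** Field densities are overwhelmingly zero (60–91%
per class in the compilation this emulates), so candidate families are
fitted by maximum likelihood — exponential, negative binomial,
zero-inflated Poisson, zero-inflated negative binomial — and compared by
AIC, ties broken toward fewer parameters. Discrete families are fitted to
integer-rounded densities; the exponential to the raw values. A
"zero-inflated binomial" candidate is interpretable only as a
presence/absence model for these data (no trial count exists), so it is
implemented as a Bernoulli presence fit and excluded from the default
comparison, selectable explicitly. Classes with fewer than 20 included
samples are flagged sparse — the threshold mirrors the six sparse classes
of the motivating compilation and is configurable — and handled by rule:
classes with no plausible milkweed (open water, barren, cultivated crops,
woody and herbaceous wetlands) become point masses at zero, and
medium-intensity development takes the parameter-wise midpoint of the
low- and high-intensity fits. The midpoint acts on parameters, not
means, so for non-linear families the implied mean differs from the
midpoint of the neighbour means — both behaviours are tested.

**Sampling and truncation.** Draws are clipped to the physical support by
default (scores to $[0,1]$, densities to $\ge 0$); rejection sampling and
raw draws are available. Clipping censors: it piles probability on the
bounds and shifts the mean of a normal score distribution upward by a few
thousandths to hundredths depending on $\mu/\sigma$. For that reason
every oracle comparison between the Monte Carlo mean and the analytic
expectation in the tests uses raw draws, where the closed-form mean is
the exact target.

**Table-driven density registries.** When only a published mean $m$ and
SD $s$ are available for a plants/ha class, the registry uses a
moment-matched negative binomial ($\mu = m$, size $= m^2/(s^2 - m)$)
rather than a truncated normal: the support is correct and both moments
are preserved exactly, whereas clipping a normal with the coefficients of
variation seen in these data (up to ~5) would inflate class means by
tens of percent. Underdispersed rows fall back to Poisson; zero rows to
point masses.

## Monte Carlo propagation

Each replicate draws one value per class and applies it to **both**
dates (`shared_across_years`, the default), so the change variance
reflects value uncertainty applied to the area deltas; an
`independent_per_year` policy exists because the underlying procedure
could be read either way, but it adds between-date draw noise that
swamps the change signal and is not used by any bundled reproduction.
The reported SE is the replicate SD divided by $\sqrt{n}$; with the
default $n = 5{,}000$ the SE identity and the expected $1/\sqrt{n}$
scaling are both under test. Fixed seed and config give bit-identical
results.

**Two percent-change conventions.** A replicate's percent change is
$100\,(T_1 - T_0)/T_0$, a ratio of correlated sums that algebraically
equals a draw-weighted average of per-class percent changes. For
low-variance registries its replicate mean sits near the analytic
percent; for heavy-tailed density registries the random weights skew the
average far from it (the Texas milkweed registry is the extreme case),
while the published headline percentages are consistent with the ratio
of mean totals. `run_habitat_change()` therefore reports both:
`mean_percent` (per-replicate average, the literal per-draw statistic)
and `percent_of_totals` (mean change over mean start total, the
convention the bundled reproductions and the acceptance script use).

**Zonal maps.** Zone-level runs share the per-class draws across all
zones within a replicate, so zonal changes sum *exactly* to the
extent-wide change, replicate by replicate — a stronger property than
summing within Monte Carlo error, and the one the tests assert. Zones
with a zero start total report missing percent change. Cross-region
mapping on a common scale uses z-score rescaling
(`mean_B + sd_B (x - \bar x_A)/sd_A`, sample SDs throughout), whose
output mean and SD equal the reference region's by construction.

## Seasonal trends

Observation stacks are reduced per-pixel by the within-season median
(spring = March–May, fall = September–November), then spatially by the
median over the extent mask, yielding one value per year. `fit_trend()`
is ordinary least squares of value on calendar year via `lm()`, with the
year centered for conditioning (the slope is invariant; the intercept is
reported on the original scale). Inference is the standard slope SE,
$t = \hat\beta/\mathrm{SE}$, and a two-sided $p$ on $n-2$ df; no
significance threshold is encoded. Exact-fit series (residual variance
numerically zero) are flagged `degenerate` rather than given a
meaningless $p$. The closed-form $\Sigma$-formula equivalence and the
~5% type-I error under null simulation are both under test.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated: landscape pairs are drawn cell-independently from mixing
proportions and a prescribed row-stochastic transition matrix, with
zones as contiguous column blocks mimicking counties, and the *realized*
transition areas returned as ground truth; surveys snap truth-plus-noise
to the five admissible levels (30 respondents and dispersion 0.15 by
default, matching the size and spread of the elicitation panel this
emulates); plot samples are zero-inflated counts with structural-zero
rates chosen inside the observed 60–91% band; seasonal stacks scatter
~11 within-season observations (the cadence of 8-day composites) around
a linear yearly mean, with defaults at the effect size the motivating
NDVI series shows (slope 0.0026/yr, noise SD 0.01 over 25 years).

What the generators deliberately omit: spatial autocorrelation (the
pipeline is area-based, so patchiness changes no tested statistic),
observation gaps and sensor artefacts in the stacks, respondent bias
structure beyond symmetric noise, and any covariance between class
values. Passing tests therefore demonstrate correctness of the
accounting, fitting and propagation machinery under known truth — not
robustness to the messiness of real rasters and surveys.

## Problem sizes and numerical conventions

Test simulations are sized for a desk machine: landscapes up to
200 × 200 cells, Monte Carlo runs of 400–5,000 replicates, 20-seed
recovery loops at $n = 1{,}000$ samples, and 500-replicate null
simulations for test size; the full suite runs in well under a minute.
Null-size loops seed successive runs with a stride (977) rather than
consecutive integers, which produced visibly correlated rejection
indicators across streams. Agreement-matrix rows must sum to 1 within
$10^{-9}$; survey scores are matched to admissible levels within
$10^{-9}$; zero-start-area classes report percent change as missing, not
zero. All areas are km² internally; percents are on the 0–100 scale.

## Known limitations

* Raster ingestion is matrix/CSV-based; no GeoTIFF reader is bundled, so
  real rasters must be exported to integer matrices or per-class area
  tables upstream.
* The weighted-SD crosswalk rule and the clip truncation default are
  conventions, not statistically optimal choices; both have documented
  alternatives and results for strongly skewed registries depend on
  them.
* Per-replicate percent change is reported but is a biased estimator of
  the percent change of expectations under heavy-tailed registries; use
  `percent_of_totals` when comparing against published headline
  percentages.
* Class values are drawn independently; any real covariance between
  classes (e.g. drought suppressing all vegetation classes at once)
  would widen the true uncertainty beyond the reported SEs.
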