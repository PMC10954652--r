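# habitatshift

Land-cover change accounting and habitat-resource estimation for the
migratory corridor of the eastern monarch butterfly (*Danaus plexippus*).

Monarchs crossing Mexico and Texas depend on two landscape resources:
nectar (fuel for the fall and spring migrations) and milkweed (*Asclepias*
spp., the larval host plant used by the first spring generation). Both are
tied to land use / land cover (LULC): a hectare of grassland, cropland or
suburb supports very different amounts of each. `habitatshift` turns paired
categorical land-cover maps (or published per-class area tables) into
estimates of how these resources changed over a roughly 20-year interval,
with uncertainty, for analysts studying habitat change for monarchs and
other pollinators.

## What the package computes

**Transition accounting.** For two classified rasters of the same extent it
tabulates the class-to-class transition matrix `A`, where `A[i, j]` is the
area (km²) moving from class *i* to class *j* (the diagonal is no-change).
Per class, *loss* = Σⱼ≠ᵢ A[i, j], *gain* = Σᵢ≠ⱼ A[i, j],
*net* = gain − loss, *gross* = gain + loss, with annualized and percent
forms, extent-wide or per county/municipality zone.

**Resource distributions.** Each land-cover class carries a per-season
distribution of resource value: normal distributions of 0–1 expert scores
aggregated from 5-level elicitation surveys (0.10 / 0.25 / 0.5 / 0.75 /
0.95), translated across classification schemes through agreement-matrix
weighted averages; or count distributions (exponential, negative binomial,
zero-inflated Poisson / negative binomial) fitted by maximum likelihood and
AIC selection to milkweed plot densities (plants/ha) that are 60–91% zeros.
Sparse classes are handled by explicit rules (known-zero classes get a
point mass at 0; a bracketed development-intensity class takes the
parameter-wise midpoint of its neighbours).

**Monte Carlo change estimation.** For each of `n` replicates (default
5,000) one value `v_c` is drawn per class and the extent totals
`T_t = Σ_c a_{c,t} · v_c` are formed for both dates; the replicate change
is `T_1 − T_0`. Means, SDs and SEs (= SD/√n) summarize the replicates, an
analytic expectation `Σ_c Δa_c · E[v_c]` provides the closed-form oracle,
zone-level runs map where change concentrates, and z-score rescaling puts
two regions measured on different scales (expert index vs plants/ha) onto
a common range.

**Seasonal trends.** Climate and NDVI observation stacks are reduced to
one value per year (per-pixel within-season median, then a spatial median
over the extent) and fitted with OLS `value ~ year`, reporting the slope,
its SE, *t* and the two-sided *p* on *n* − 2 df.

A synthetic-data module generates every input with known ground truth
(Markov-transition landscape pairs, Likert surveys, zero-inflated plot
counts, trending seasonal stacks, Dirichlet agreement matrices), so the
entire pipeline runs and is tested without any external download.

## Worked example

Change table for the Texas study extent (2001–2019, bundled reference
areas), then the milkweed-change estimate:

```r
library(habitatshift)

tx <- run_change_tables(list(region = "texas"))
tx[tx$class_id %in% c("cropland", "pasture", "dev_med"), ]
#>   class_id start_area end_area  loss  gain   net gross annual percent_annual
#> 1 cropland      43589    47101  1290  4802  3512  6092   195.          0.448
#> 2 dev_med        5378     8127    35  2784  2749  2819   153.          2.84
#> 3 pasture       72955    67612  5875   532 -5343  6407  -297.         -0.407
```

Cropland gained a net 3,512 km² (gross turnover 6,092 km², ~195 km²/yr);
pasture/hay lost a net 5,343 km². Propagating all 15 class changes through
the per-class milkweed-density distributions:

```r
hc <- run_habitat_change(list(region = "texas", n_reps = 5000, seed = 11))
hc[hc$resource == "milkweed", ]
#>   resource season expected_change mean_change se_change percent_of_totals  total_t0
#> 1 milkweed spring       -30188110   -30812264   1223903            -2.947 1.035e+09
```

Reading the row: the extent held an expected 1.035 × 10⁹ milkweed plants
in 2001 (`total_t0`); the closed-form expected change is −3.02 × 10⁷
plants; the 5,000-replicate Monte Carlo mean change, −3.08 × 10⁷ ± 1.2 × 10⁶
(SE), agrees within Monte Carlo error, and the decline is −2.9% of the
2001 stock (`percent_of_totals`). The same call reports fall and spring
nectar-score changes; `run_trends()` produces the seasonal trend-fit
table.

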