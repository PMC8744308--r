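---
title: "Walkable funded access and spatial equity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walkable funded access and spatial equity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundedaccess)
```

## The question and the model

City health departments contract nonprofit providers to deliver services
at specific locations. Whether those contracted dollars are *within
walkable reach* of high-need neighborhoods is a spatial question that the
usual accounting — summing contract amounts at headquarters addresses
inside administrative boundaries — answers badly, for two reasons: many
services are delivered at satellite sites, and residents cross boundary
lines on foot. This package implements both the naive **container**
accounting (headquarters-only and all-sites variants, so the two can be
contrasted) and the **two-step floating catchment area (2SFCA)** measure
of funded access.

With sites $j$ carrying allocated dollars $S_j$, blocks $i$ with
population $D_i$, walking minutes $t_{ij}$, and threshold $T$:

$$R_j = \frac{S_j}{\sum_i D_i \, I(t_{ij} < T)}, \qquad
  A_i = \sum_j R_j \, I(t_{ij} < T).$$

$A_i$ is in dollars per person: the funding intensity within walkable
reach of block $i$. Catchment weights are binary and sharp — no
distance-decay kernel — and the indicator is the *strict* inequality
$t < T$; a pair at exactly $T$ minutes is outside the catchment. Both
choices are deliberate: they match the classic formulation of the
measure, and the boundary rule is exposed as `inclusive = TRUE` for
sensitivity analysis only.

Two model properties worth knowing:

* **Conservation.** $\sum_i D_i A_i$ equals the total supply at sites
  whose catchment contains any population. The implementation preserves
  this identity to machine precision, and the test suite asserts it on
  every scenario. Sites with an empty populated catchment get $R_j = 0$
  with a `zero_demand` flag (rather than NaN), which keeps the identity
  valid over the remaining sites.
* **Non-monotonicity in $T$.** $A_i$ is *not* monotone in the threshold
  when both steps use the same $T$: enlarging $T$ adds sites to block
  $i$'s catchment but also adds population to every site's denominator.
  One site of \$100 with a 10-person block at 5 minutes and a
  1000-person block at 25 minutes gives that first block $A = 10$ at
  $T = 10$ but $A \approx 0.10$ at $T = 30$. Conservation makes this
  unavoidable: total population-weighted access is pinned to total
  supply, so growing catchments redistribute access rather than grow it.
  The site-count and population-coverage metrics *are* monotone in $T$,
  as is $A_i$ when the step-1 ratios are held fixed; the test suite
  distinguishes these cases explicitly.

## Funding allocation

Contracts are filtered to in-scope, site-specific services (citywide
contracts and contracts without any delivery site are excluded, each
exclusion logged with a reason). A contract with explicit per-site shares
is split as `amount × share` (shares must sum to 1 within $10^{-9}$).
Without shares, the amount is divided equally among the headquarters and
all satellite sites. The `hq_delivers` flag (default `TRUE`) exists
because administrative data often cannot distinguish a headquarters that
delivers services from one that only administers them; with
`hq_delivers = FALSE` the equal split covers satellites only and the
headquarters is recorded at \$0. Every allocation stage conserves
dollars exactly, and the tests assert conservation at each step.

## Walking times

Travel times run over an undirected street network (pedestrian travel has
no one-way restrictions) with Dijkstra shortest paths — one single-source
sweep per distinct origin node, never per pair. The unit conversion is
fixed at 1 mile = 1609.344 m, so the default 3 mph is 80.4672 m/min;
minutes are carried as floating values and never rounded before
thresholding. Unreachable pairs are `Inf` minutes with an explicit
`reachable()` accessor — `Inf < T` is always false, so no sentinel value
can leak through a threshold. A pure-R brute-force Dijkstra oracle in the
test helpers (independent of the igraph-backed implementation) verifies
the matrix bitwise on dozens of random networks.

## Hardship and classification

The hardship index combines six tract-level indicators — crowded housing,
poverty, unemployment, low education, dependents (percentages) and
per-capita income (dollars). The agency that publishes the index does not
publish its exact construction, so the package uses the classic
bounded construction: min–max scale each component to $[0, 100]$ across
tracts, invert income (higher income, lower hardship), and average the
six. A component constant across tracts contributes 0, with a warning.
Users with a precomputed index can supply it directly to
`tercile_classify()`.

Terciles are rank-based: group sizes differ by at most one, remainders go
to the lower groups first (10 tracts split 4/3/3), and ties break by
stable unit id, which makes the classification invariant under strictly
monotone transforms of the values (property-tested on 1,000 random
vectors).

Block metrics are averaged to tracts *unweighted* by default (population
weighting is available and reported when used); blocks that can reach no
site are excluded from the nearest-minutes mean and counted. Spending
terciles are computed on the tract mean 2SFCA value, and the 3×3
hardship-by-spending table is the equity map's backbone: off-diagonal
cells with high hardship and low spending are candidate access gaps.

## The synthetic city: what it emulates, and what it does not

Real contract, site, and block data of this kind belong to the issuing
health department and are not public, so the generator builds cities with
the statistical structure the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| grid, edge length | 40×40 nodes, 200 m | ~8 km city span, several walksheds across |
| edge removal | 0.1 | path heterogeneity while staying connected |
| blocks, tract size | 4,800 blocks, 8/tract | ~600 tracts, the reference scenario scale |
| block population | NB(mean 58, size 1.5) | big-city block mean (~2.7M people / ~46k blocks); over-dispersed counts |
| hardship gradient | strength 0.8, noise sd 5 | strong but noisy west–east segregation |
| providers, satellites | 150, Poisson(2) | a few hundred delivery sites for ~100 in-scope contracts |
| contract amounts | lognormal, mean \$300k | tens of \$M citywide, right-skewed |
| program mix | 70/16/6/5/3 % | HIV/STI-dominated funding mix |
| citywide share | 0.31 | ~69% of contracts are site-specific |
| explicit shares | 0.25 | most contracts lack per-site shares |
| walk speed, T | 3 mph, 30 min | standard walkability assumptions |

The `hq_downtown` preset sharpens the placement biases
(`hq_low_hardship_bias = 0.9`, `satellite_high_hardship_bias = 0.8`,
seed 7): headquarters concentrate in affluent tracts while delivery
happens disproportionately in medium/high-hardship tracts. Under this
preset the container contrast reverses exactly as intended — the
low-hardship funding share is far higher under headquarters-only
accounting than under all-sites accounting — and that reversal is an
acceptance-tested property.

Deliberate simplifications, hence what a green test does *not*
establish:

* Hardship varies along a **one-dimensional** west–east gradient. Real
  segregation is patchier; in particular, medium-hardship tracts here
  occupy the geometric center of the city and can reach supply on both
  sides, so tract-mean 2SFCA access comes out nearly flat across
  hardship groups rather than highest in high-hardship areas. The
  reversal of funding *shares* is robust to this; fine-grained group
  orderings of the access surface are geometry-dependent and should not
  be read as predictions about any real city.
* Block centroids sit exactly on network nodes — no snapping error
  (`snap_to_node()` exists for external data).
* Satellites are sampled uniformly within the medium+high stratum; no
  extra concentration in the highest-need tracts.
* One contract per provider, one year, no intermediaries, no
  non-contract funding streams.

## Reproducibility and numerics

A single scenario seed fans out to per-stage seeds via a fixed Lehmer
step (`stage_seed()`), so each generation stage is individually
reproducible and the full pipeline is deterministic: identical
configurations yield identical stage checksums (asserted in the tests).
Dollar amounts are carried as doubles and only rounded at report render
time; allocation sums are validated to $10^{-6}$ dollars. Degenerate
inputs have defined behavior throughout: empty block lists, zero
populations (per-capita values become `NA`, never a division by zero),
zero-demand sites, unreachable blocks, and constant hardship components
all have explicit, tested paths.

## Known limitations

Potential access only (no utilization data); binary catchments (no
gravity/enhanced-2SFCA kernels); pedestrian travel only; demand is total
block population rather than a program-specific target population —
`supply_ratio()` accepts any per-block demand weights should such a
proxy be available.
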