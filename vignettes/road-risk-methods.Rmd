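---
title: "Assessing road risk for apex predators: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing road risk for apex predators: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Roads kill predators directly through vehicle collisions and indirectly by
fragmenting habitat, severing gene flow and opening remote areas to
poaching. Because terrestrial apex predators range widely and live at low
densities, they are disproportionately sensitive to road networks. This
package implements a global screening model for that hazard: a per-species
**road risk** score, a per-pixel **cumulative road risk** surface, and an
impact assessment for **proposed** road developments. This vignette
explains the model, its assumptions, its tunable parameters, and the design
choices made where the method leaves room.

## The species risk model

Risk follows the classical likelihood-times-severity decomposition:

$$\mathrm{Risk}_i = \mathrm{Exposure}_i^{*} \cdot \mathrm{Vulnerability}_i^{*}$$

**Exposure** is the square root of the mean road density within the range
of species $i$:

$$\mathrm{Exposure}_i = \sqrt{\mathrm{RoadDensity}_i},$$

where road density is total road length (m) inside the species'
distribution divided by distribution area (km²). `mean_road_density()`
computes this as the area-weighted mean of the density raster over the
range cells, which is algebraically identical to length-over-area; the
square root damps the very long right tail of road densities.

**Vulnerability** aggregates four max-normalized components:

$$\mathrm{Vulnerability}_i = nPA_i^{*} + IUCN_i^{*} + 0.5\,TH_i^{*} + 0.5\,BM_i^{*}$$

* $nPA$ — the fraction of range area outside protected areas;
* $IUCN$ — Red List status on the ordinal scale LC = 1 … CR = 5;
* $TH$ — the count of threat types listed for the species;
* $BM$ — the body-mass class: small (8–15 kg) = 1, medium (15–25 kg) = 2,
  large (25–100 kg) = 3, very large (> 100 kg) = 4. Body mass proxies home
  range size and hence road-encounter likelihood.

Unprotected range and Red List status carry full weight; threat count and
body mass half weight, reflecting their weaker link to road-specific harm.
The starred superscript means division by the maximum over the analyzed
species set, applied to each component and again to exposure and
vulnerability, so the final risk lies in $[0, 1]$.

Three consequences of max-normalization deserve emphasis:

* **The species set is an input.** Adding or removing one species rescales
  every risk. `risk_table()` therefore always takes the full traits table
  and range set together.
* **Risks are scale-free in density.** Multiplying all densities by a
  constant leaves all risks unchanged (tested property).
* **Degenerate sets fail loudly.** If any component has maximum zero
  (e.g. all densities zero), normalization is undefined and `risk_table()`
  raises an explicit error rather than producing NaNs.

The published class ranges for body mass share endpoints (15, 25, 100 kg).
We resolve them lower-inclusive/upper-exclusive, with the shared top of
each printed range joining the class above — `[8,15) = 1`, `[15,25) = 2`,
`[25,100] = 3`, `>100 = 4` — and accept a `bm_category` override column in
the traits table for species the analyst wants to place manually. Masses
below 8 kg (species kept because they are the main predator of their
ecosystem despite the size threshold) fall in class 1 with a warning.

## The cumulative surface and impact levels

Per pixel, risks are stacked as

$$\mathrm{CumulativeRisk}_{px} = SSR_{px} + \beta \cdot PA_{px},$$

with $SSR$ the sum of risk over species present, $\beta$ their mean risk
and $PA$ a binary protected flag. On a protected pixel holding $n$ species
this equals $SSR\,(1+1/n)$ — protection up-weights a pixel in proportion to
the typical risk of its community, marking protected predator strongholds.
Where no species is present we define $\beta = 0$, so an empty protected
pixel scores 0; the formulation leaves this case open and zero is the only
choice that keeps "no species, no risk" exact.

Reported impact levels discretize the surface into ten classes.
The mapping from the continuous value is not uniquely determined by the
method description, so `impact_levels()` defaults to **equal-width bins on
$(0, \max]$ with ceiling assignment** — `level = ceil(10·value/max)` —
which is deterministic, preserves ordering, and puts the maximum-attaining
pixels exactly at level 10; cells with value 0 get level 0. A quantile
binning mode exists as an alternative, and the binning mode plus the
normalizing maximum are recorded in every run manifest. For regional
windows, pass the full-extent maximum via `max_value` so levels stay
comparable across regions. Because the binning is a convention, all
level-dependent tests are property-based (ordering, partition of lengths,
percentages summing to 100) rather than value-matching.

## Screening proposed roads

`segment_by_cell()` cuts each proposed polyline exactly at raster cell
boundaries (segments are straight in lon/lat; each piece is measured
geodesically on WGS84) and `assign_impact()` tags each piece with the
cumulative risk and impact level of its pixel. From there:

* `level_length_distribution()` — km and % of network length per level;
* `species_crossing()` — length of network inside each species' range
  polygon, as a share of network length and relative to range area. This
  is computed vector-on-vector (polyline clipped against the range
  polygon), avoiding a second discretization through the raster;
* `pa_intersections()` — per protected area: direct intersection flag,
  intersected length, and whether the PA lies within a 10-km buffer of the
  network.

Buffer membership is evaluated as *minimum geodesic distance between the
polygon and the network ≤ buffer width*. For membership testing this is
exactly equivalent to constructing an explicit geodesic buffer polygon and
intersecting, but has no projection distortion; the implementation
combines point-to-geodesic-segment distance (via geosphere) with
containment tests on boundaries densified to ~2 km. A tangent single-point
touch counts as a direct intersection (with length 0), and PA features are
deduplicated by id before counting, since protected-area databases contain
overlapping designations — a convention that matters when comparing counts
against other analyses.

## Grid, areas and measurement conventions

The analysis grid is a regular geographic lattice (default 5 arc-minutes,
the resolution of the gridded road-inventory data the pipeline is designed
to ingest). It is north-up with half-open cells
$[w, e) \times (s, n]$, so every point belongs to exactly one cell.
Rasterization of range and PA polygons uses the **cell-center rule**: a
cell is presence if its center is covered. The rule is deterministic and
equals an exhaustive point-in-polygon test at all centers (tested against
an independent implementation); an area-coverage threshold mode is
available but not default.

Cell areas use the spherical closed form $R^2 \Delta\lambda
(\sin\varphi_2 - \sin\varphi_1)$ with the authalic radius
$R = 6371.0072$ km, which sums exactly to $4\pi R^2$ globally. Lengths of
roads are geodesic on the WGS84 ellipsoid. Mixing an authalic-sphere area
with ellipsoidal lengths introduces a sub-percent inconsistency in
densities; it is deliberate (areas get an exact conservation property,
lengths get the best available measure) and covered by the 0.5–1%
tolerances used throughout the tests. Geometries crossing the antimeridian
are rejected with an explicit error rather than silently wrapped; none of
the intended use regions require them.

Road-type aggregation sums the density layers the caller passes — by
convention types 1–4 (highways, primary, secondary, tertiary). Type 5
(local roads) is spatially biased toward developed countries and is
excluded by default; the pipeline configuration emits a warning and drops
it unless `force_type5: true`. Nodata cells count as zero when any sibling
layer has data and stay nodata only where all layers are nodata.

## Wildlife-vehicle-collision records

The WVC component is a record model, not a spatial one: one row per study
× species × country with individual counts and study duration. Missing
counts and missing durations are both imputed as 1 — the convention of the
underlying compilation — and the per-record annual rate is
individuals/years. The per-country "collisions in a single year" figure is
implemented as the **sum of per-record annual rates**; the alternative
reading (the maximum over records) is available via `per_year_max = TRUE`
but the sum-of-rates reading follows directly from the rate definition and
is the default. Sampling effort per country is the sum of study durations.
Species names match case-insensitively on canonical binomials.

## The synthetic world

`simulate_world()` generates complete pipeline inputs from one seed. The
default geometry is chosen so that ground truth is closed-form, not merely
independent code:

* ranges are axis-aligned rectangles snapped to cell boundaries, so the
  rasterized cell set is known exactly;
* roads are meridian lines of varying per-region intensity; a meridian's
  geodesic length across a grid row is a single `distGeo` evaluation, so
  per-cell road lengths, densities, coverage and the whole risk table can
  be computed by direct arithmetic outside the pipeline;
* protected areas are cell-snapped rectangles, making $nPA$ exact.

The default world uses a 36 × 36 half-degree window with 6 species, 25%
protected-area coverage and 2–12 roads per species region — small enough
that the full suite runs in seconds, large enough that every species has
hundreds of cells. `make_benchmark_world()` builds a deterministic
36-species benchmark whose constructed gradient (a top species with roads
through 35 of its 36 cells and the highest density, a runner-up at two
thirds of that density, a road-free boreal-like species at the bottom)
fixes the expected risk *ranking* by construction; integration tests
assert the pipeline reproduces that ranking, not any particular printed
value. Blob-shaped ranges and random-walk roads are available for fuzzing
and are checked against brute-force densify-and-bin oracles instead of
closed forms.

What the synthetic world does **not** emulate: the spatial autocorrelation
of real road networks, coastline-clipped ranges, multi-polygon WDPA
designations with overlapping boundaries, and the heavy-tailed size
distribution of real range maps. Passing tests therefore demonstrate
correctness of the computations, not calibration against real-world data;
running the pipeline on the real gridded road inventory, Red List range
maps and WDPA polygons requires converting them to the package's ASCII
grid/GeoJSON interchange formats.

## Numerical choices and degenerate inputs

* Line clipping treats segments as straight in lon/lat and splits them at
  graticule lines by exact linear interpolation; the resulting pieces are
  measured geodesically. Agreement with a fine densify-and-bin oracle is
  within 0.5% at the cell sizes used.
* Point-in-polygon uses even-odd ray casting with an explicit on-boundary
  test, so boundary points count as inside deterministically.
* Empty polygon sets rasterize to all-zero with a warning; empty species
  ranges and all-zero cumulative layers raise errors naming the offender.
* Ties in the risk ranking are broken alphabetically by species name.
* All simulation randomness flows from the single `seed` in
  `world_params()`; the generator saves and restores the caller's RNG
  state.

## Known limitations

* Risk is strictly cellwise: no distance decay away from roads, no
  smoothing, no barrier/connectivity modeling.
* The global scale underestimates local impacts on wide-ranging species;
  populations at a range edge can be far more exposed than the range mean
  suggests.
* The impact-level binning is a reporting convention; analyses that depend
  on absolute level values should report the binning mode and maximum from
  the run manifest alongside.
* Raster interchange is ESRI ASCII grid and vector interchange GeoJSON;
  GeoTIFF/Shapefile sources must be converted upstream (e.g. with GDAL:
  `gdal_translate -of AAIGrid` and `ogr2ogr -f GeoJSON`).
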