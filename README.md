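# roadrisk

Road networks are among the most pervasive threats to terrestrial apex
predators: vehicle collisions, habitat fragmentation, genetic isolation and
poaching access all scale with road density. **roadrisk** implements a
global screening framework for this hazard, aimed at conservation
scientists and infrastructure planners who need to rank species by their
risk from the *current* road network and to locate high-impact segments of
*proposed* road developments.

## The model

Per species *i*, risk is likelihood × severity, both max-normalized over
the analyzed species set (the `*` superscript):

```
Risk_i        = Exposure_i* · Vulnerability_i*
Exposure_i    = sqrt(RoadDensity_i)            # mean m/km² over the range
Vulnerability_i = nPA_i* + IUCN_i* + 0.5·TH_i* + 0.5·BM_i*
```

with `nPA` the unprotected fraction of the range, `IUCN` the Red List
status (LC = 1 … CR = 5), `TH` the listed threat count, and `BM` the
body-mass class (8–15 kg = 1, 15–25 kg = 2, 25–100 kg = 3, > 100 kg = 4).
Per pixel, species risks are stacked with a protected-area bonus:

```
CumulativeRisk_px = SSR_px + β · PA_px
```

where `SSR` is the sum of risks of species present, `β` their mean and
`PA` a binary protected flag. Proposed roads are split at raster cell
boundaries, each segment inherits its pixel's cumulative risk and 1–10
impact level, and reports give % road length per level, crossing lengths
per species range, and protected areas intersected directly or within a
10-km buffer.

Rasters live on a regular geographic lattice (default 5 arc-minutes);
lengths are geodesic (WGS84, via **geosphere**); cell areas use the
authalic-sphere closed form. Raster interchange is ESRI ASCII grid, vector
interchange GeoJSON — convert GeoTIFF/Shapefile sources with GDAL
(`gdal_translate -of AAIGrid`, `ogr2ogr -f GeoJSON`).

## Worked example

Everything runs on a seeded synthetic world with closed-form ground truth,
so no downloads are needed:

```r
library(roadrisk)

w      <- simulate_world(world_params(seed = 7))
areas  <- cell_areas(w$grid)
ranges <- lapply(w$range_polygons, rasterize_presence, grid = w$grid)
pa     <- rasterize_presence(w$pa_polygons, w$grid)
dens   <- line_density(w$road_features, w$grid, areas)

rt <- risk_table(w$traits, ranges, dens, pa, areas)
rt[, c("species", "road_density", "exposure_star", "vulnerability_star", "risk")]
#>   species       road_density exposure_star vulnerability_star  risk
#> 1 Predator sp04        24.0          0.911              0.944 0.859
#> 2 Predator sp01        27.2          0.969              0.882 0.854
#> 3 Predator sp02        27.5          0.974              0.852 0.830
#> 4 Predator sp05        15.1          0.723              1     0.723
#> 5 Predator sp03        29.0          1                  0.530 0.530
#> 6 Predator sp06         9.34         0.568              0.678 0.385
```

`sp03` has the highest road density (29 m/km², so `exposure_star = 1`) but
a well-protected, lightly threatened profile drags its vulnerability down;
`sp04` tops the ranking because moderate exposure meets high
vulnerability. Screening the world's proposed roads:

```r
cum  <- cumulative_risk(rt, ranges, pa)
lv   <- impact_levels(cum, 10)
segs <- assign_impact(segment_by_cell(w$future_roads, w$grid), cum, lv)
level_length_distribution(segs, 10)   # non-empty levels shown
#>   level length_km   pct
#> 1     0      860.  36.8
#> 2     2      312.  13.3
#> 3     3      801.  34.3
#> 4     6      365.  15.6

pt <- pa_intersections(w$future_roads, w$pa_polygons, buffer_km = 10)
attr(pt, "n_direct"); attr(pt, "n_buffered")
#> 5 directly intersected, 5 within the 10-km buffer
```

So 15.6% of the proposed network falls on level-6 pixels (risk hotspots,
here protected cells shared by several high-risk species), and five
protected areas would be crossed outright. The per-level percentages
always sum to 100, and directly intersected PAs are always a subset of the
buffered set.

`run_pipeline("config.yaml")` executes the same chain from a YAML
configuration (per-type density rasters, range/PA GeoJSON, traits and WVC
CSVs) and writes all tables, rasters and a manifest to an output
directory. A thin CLI over the same functions is in `inst/cli/roadrisk.R`
(subcommands `simulate`, `run`, `wvc-summary`).

Wildlife-vehicle-collision records are handled by `normalize_wvc()`
(missing individual counts and study durations are imputed as 1),
`wvc_country_summary()` (single-year collision totals = sum of per-record
annual rates; effort = sum of study-years) and `wvc_species_summary()`
(totals and universe coverage).

## Documentation

The methods vignette (`vignettes/road-risk-methods.Rmd`) covers the model
and its assumptions, the normalization conventions, binning and buffer
design choices, the synthetic-world construction, and known limitations.
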