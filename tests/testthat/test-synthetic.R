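test_that("the same seed reproduces a byte-identical world", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  w1 <- simulate_world(world_params(seed = 12), dir = d1)
  w2 <- simulate_world(world_params(seed = 12), dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  # a different seed changes the geometry
  w3 <- simulate_world(world_params(seed = 13))
  expect_false(identical(w1$truth$per_species$density,
                         w3$truth$per_species$density))
})

test_that("zero protected-area coverage forces nPA = 1 in ground truth", {
  w <- simulate_world(world_params(seed = 4, pa_coverage = 0))
  expect_equal(w$truth$per_species$npa, rep(1, w$params$n_species))
  expect_equal(length(w$pa_polygons), 0)
})

test_that("pipeline agrees with the closed-form lattice ground truth", {
  w <- simulate_world(world_params(seed = 31, n_species = 5))
  g <- w$grid
  areas <- cell_areas(g)
  ranges <- lapply(w$range_polygons, rasterize_presence, grid = g)
  pa <- rasterize_presence(w$pa_polygons, g)
  # density via the vector route (splitting + geodesic measurement)
  dens_geom <- line_density(w$road_features, g, areas)
  rt <- suppressWarnings(risk_table(w$traits, ranges, dens_geom, pa, areas))
  tr <- w$truth$per_species
  m <- match(tr$species, rt$species)
  expect_equal(rt$road_density[m], tr$density, tolerance = 5e-3)
  expect_equal(rt$npa[m], tr$npa, tolerance = 1e-9)
  expect_equal(rt$road_coverage[m], tr$coverage, tolerance = 1e-9)
  expect_equal(rt$range_area_km2[m], tr$area_km2, tolerance = 1e-9)
  expect_equal(rt$risk[m], tr$risk, tolerance = 5e-3)
  # rasterized range cells are exactly the rectangle cell sets
  for (i in seq_along(ranges)) {
    rc <- w$truth$range_rects[[i]]
    expected <- matrix(0, g$nrow, g$ncol)
    expected[rc["r0"]:rc["r1"], rc["c0"]:rc["c1"]] <- 1
    expect_equal(ranges[[i]]$values, expected)
  }
  # cumulative surface matches the direct per-cell evaluation
  cum <- cumulative_risk(rt, ranges, pa)
  direct <- {
    ssr <- matrix(0, g$nrow, g$ncol); n <- matrix(0, g$nrow, g$ncol)
    for (s in names(ranges)) {
      r <- rt$risk[rt$species == s]
      ssr <- ssr + r * ranges[[s]]$values
      n <- n + ranges[[s]]$values
    }
    ssr + ifelse(n > 0, ssr / pmax(n, 1), 0) * pa$values
  }
  expect_equal(cum$values, direct, tolerance = 1e-12)
})

test_that("lattice-mode meridian lengths carry closed-form geodesic totals", {
  w <- simulate_world(world_params(seed = 2, n_species = 3))
  g <- w$grid
  areas <- cell_areas(g)
  ld <- line_density(w$road_features, g, areas)
  L_truth <- Reduce(`+`, w$truth$road_length_by_type)
  got <- ld$values * areas$values
  on <- L_truth > 0
  expect_lt(max(abs(got - L_truth)[on] / L_truth[on]), 5e-3)
})

test_that("blob and walk modes produce valid worlds for fuzzing", {
  w <- simulate_world(world_params(seed = 6, range_mode = "blob",
                                   road_mode = "walk"))
  expect_null(w$truth)
  g <- w$grid
  ranges <- lapply(w$range_polygons, rasterize_presence, grid = g)
  expect_true(all(vapply(ranges, function(r) sum(r$values), 0) >= 0))
  ld <- line_density(w$road_features, g)
  # brute-force oracle on the irregular network
  oracle <- Reduce(`+`, lapply(w$road_features, function(f)
    densify_bin_oracle(f$coords, g)))
  got <- ld$values * cell_areas(g)$values
  expect_lt(max(abs(got - oracle)) / sum(oracle), 5e-3)
})

test_that("the 36-species benchmark world has the constructed ranking", {
  w <- make_benchmark_world()
  tr <- w$truth$per_species
  expect_equal(nrow(tr), 36)
  # the constructed top species ranks first in risk and density
  expect_equal(which.max(tr$risk), 1L)
  expect_equal(which.max(tr$density), 1L)
  # ~97% of its range covered by roads (35 of 36 cells)
  expect_equal(tr$coverage[1], 35 / 36)
  # runner-up density about two thirds of the top
  expect_equal(tr$density[2] / tr$density[1], 2 / 3, tolerance = 0.05)
  # the road-free boreal-like species ranks last in exposure
  expect_equal(which.min(tr$exposure), 36L)
  expect_equal(tr$density[36], 0)
  # pipeline ranking equals ground-truth ranking
  g <- w$grid
  areas <- cell_areas(g)
  ranges <- lapply(w$range_polygons, rasterize_presence, grid = g)
  pa <- rasterize_presence(w$pa_polygons, g)
  dens <- line_density(w$road_features, g, areas)
  rt <- risk_table(w$traits, ranges, dens, pa, areas)
  m <- match(tr$species, rt$species)
  expect_equal(order(-rt$risk[m]), order(-tr$risk))
  expect_equal(rt$risk[m], tr$risk, tolerance = 1e-6)
  # WVC table covers 30 of the 36 species
  expect_equal(wvc_species_summary(w$wvc, w$traits$species)$coverage, 30)
})
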