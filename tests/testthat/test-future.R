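test_that("segments partition each road and land in the right cells", {
  g <- grid_spec(30, c(0, 3, 0, 3))
  # road entirely inside one cell
  inside <- road_feature(cbind(c(0.1, 0.4), c(2.6, 2.9)), id = "one")
  s1 <- segment_by_cell(inside, g)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$length_km, geodesic_length_m(inside$coords) / 1000)
  expect_equal(c(s1$cell_row, s1$cell_col), c(1, 1))
  # straight road crossing exactly two cells
  two <- road_feature(cbind(c(0.25, 0.75), c(2.75, 2.75)), id = "two")
  s2 <- segment_by_cell(two, g)
  expect_equal(nrow(s2), 2)
  expect_equal(sum(s2$length_km), geodesic_length_m(two$coords) / 1000,
               tolerance = 1e-6)
  # zig-zag across the grid: per-cell lengths match the densify oracle
  set.seed(21)
  zig <- road_feature(cbind(stats::runif(8, 0.05, 2.95),
                            stats::runif(8, 0.05, 2.95)), id = "zig")
  sz <- segment_by_cell(zig, g)
  oracle <- densify_bin_oracle(zig$coords, g)
  per_cell <- matrix(0, g$nrow, g$ncol)
  for (r in seq_len(nrow(sz)))
    per_cell[sz$cell_row[r], sz$cell_col[r]] <-
      per_cell[sz$cell_row[r], sz$cell_col[r]] + sz$length_km[r] * 1000
  expect_lt(max(abs(per_cell - oracle)) / sum(oracle), 5e-3)
  expect_equal(sum(sz$length_km) * 1000, geodesic_length_m(zig$coords),
               tolerance = 1e-3)
  # features outside the extent are named in the error
  expect_error(segment_by_cell(road_feature(cbind(c(1, 5), c(1, 1)),
                                            id = "lost"), g),
               "lost", class = "roadrisk_geometry_error")
})

test_that("segments inherit pixel risk values and levels", {
  g <- grid_spec(60, c(0, 5, 0, 1))
  one <- binary_layer(g, 1)
  cu <- cumulative_risk(tibble::tibble(species = "a", risk = 1),
                        list(a = one), binary_layer(g, 0))
  cu$values <- matrix(c(1, 0.31, 0, 0.5, 0.9), 1); cu$ssr <- cu$values
  lv <- impact_levels(cu, 10)
  road <- road_feature(cbind(c(0.1, 4.9), c(0.5, 0.5)), id = "r")
  segs <- assign_impact(segment_by_cell(road, g), cu, lv)
  expect_equal(segs$cum_risk, as.vector(cu$values)[segs$cell_col])
  expect_equal(segs$level[segs$cell_col == 1], 10L)
  expect_equal(segs$level[segs$cell_col == 2], 4L)
  expect_equal(segs$level[segs$cell_col == 3], 0L)
  # uniform layer: every segment the same level
  cu$values <- matrix(0.4, 1, 5)
  lvu <- impact_levels(cu, 10)
  su <- assign_impact(segment_by_cell(road, g), cu, lvu)
  expect_equal(length(unique(su$level)), 1)
})

test_that("level length distribution reports all levels and sums to 100%", {
  segs <- tibble::tibble(road_id = "r", cell_row = 1, cell_col = 1:6,
                         length_km = c(10, 10, 10, 5, 5, 5),
                         level = c(3L, 4L, 5L, 0L, 0L, 0L))
  tab <- level_length_distribution(segs, 10)
  expect_equal(nrow(tab), 11)  # levels 0..10, empty ones as 0
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_equal(tab$pct[tab$level %in% 3:5], rep(100 * 10 / 45, 3))
  one_level <- segs; one_level$level <- 7L
  t1 <- level_length_distribution(one_level, 10)
  expect_equal(t1$pct[t1$level == 7], 100)
  expect_error(level_length_distribution(segs[0, ], 10),
               class = "roadrisk_validation_error")
})

test_that("species crossings measure network length inside each range", {
  g <- grid_spec(30, c(0, 4, 0, 4))
  net <- list(road_feature(cbind(c(0.5, 3.5), c(2, 2)), id = "w"))
  full <- rect_poly(0, 4, 0, 4, id = "full")
  half <- rect_poly(0, 2, 0, 4, id = "half")    # boundary at the midpoint
  off <- rect_poly(0, 4, 3.2, 4, id = "off")
  sc <- species_crossing(net, list(all = full, west = half, none = off),
                         c(all = 100, west = 50, none = 10))
  expect_equal(sc$pct_of_network[sc$species == "all"], 100)
  expect_equal(sc$crossing_km[sc$species == "none"], 0)
  expect_equal(sc$pct_of_network[sc$species == "none"], 0)
  # geodesic midpoint of a parallel-running road is its lon midpoint
  expect_equal(sc$pct_of_network[sc$species == "west"], 50, tolerance = 5e-3)
  # length relative to range area
  expect_equal(sc$km_per_km2_range[sc$species == "all"],
               sc$crossing_km[sc$species == "all"] / 100)
  expect_true(all(sc$pct_of_network >= 0 & sc$pct_of_network <= 100))
})

test_that("PA screening separates direct, buffered and distant areas", {
  km_deg <- 111.32  # meridian degree, used only to place fixtures
  road <- road_feature(cbind(c(5, 5), c(-1, 1)), id = "r")
  circle <- function(clon, clat, r_km, id) {
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    r <- r_km / km_deg
    polygon_feature(cbind(clon + r * cos(th), clat + r * sin(th)), id = id)
  }
  containing <- rect_poly(4, 6, -2, 2, id = "contains")
  near9 <- circle(5 + 9 / km_deg, 0, 0.5, "near9")   # centroid 9 km east
  far50 <- circle(5 + 50 / km_deg, 0, 0.5, "far50")
  tab <- pa_intersections(road, list(containing, near9, far50), buffer_km = 10)
  expect_equal(tab$direct, c(TRUE, FALSE, FALSE))
  expect_equal(tab$within_buffer, c(TRUE, TRUE, FALSE))
  # PA containing the whole network: intersected length = total length
  expect_equal(tab$length_km[1], geodesic_length_m(road$coords) / 1000,
               tolerance = 1e-6)
  expect_equal(attr(tab, "n_direct"), 1)
  expect_equal(attr(tab, "n_buffered"), 2)
  # direct set is contained in the buffered set for any positive buffer
  expect_true(all(!tab$direct | tab$within_buffer))
  # shrinking the buffer never adds PAs
  tab5 <- pa_intersections(road, list(containing, near9, far50), buffer_km = 5)
  expect_true(all(!tab5$within_buffer | tab$within_buffer))
  # duplicated ids are collapsed before counting
  tabdup <- pa_intersections(road, list(near9, near9), buffer_km = 10)
  expect_equal(nrow(tabdup), 1)
})
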