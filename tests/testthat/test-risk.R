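test_that("body-mass classes follow the published bounds", {
  expect_equal(body_mass_category(150), 4L)
  expect_equal(body_mass_category(50), 3L)
  expect_equal(body_mass_category(10), 1L)
  expect_equal(body_mass_category(c(101, 100, 25, 24.9, 15, 14.9, 8)),
               c(4L, 3L, 3L, 2L, 2L, 1L, 1L))
  expect_warning(expect_equal(body_mass_category(6), 1L))
  expect_error(body_mass_category(0), class = "roadrisk_validation_error")
})

test_that("IUCN status maps to the 1-5 ordinal scale", {
  expect_equal(iucn_value(c("LC", "NT", "VU", "EN", "CR")), 1:5)
  expect_equal(iucn_value(" lc "), 1L)
  expect_error(iucn_value("EX"), class = "roadrisk_validation_error")
})

test_that("exposure is the square root of road density", {
  expect_equal(exposure(0), 0)
  expect_equal(exposure(100), 10)
  expect_equal(round(exposure(303), 3), 17.407)
  expect_error(exposure(-1), class = "roadrisk_validation_error")
})

test_that("mean road density is the area-weighted range mean", {
  g <- grid_spec(30, c(0, 2, 0, 2))
  areas <- cell_areas(g)
  rng <- binary_layer(g, 1)
  # uniform density over any range is recovered exactly
  expect_equal(mean_road_density(rng, density_layer(g, 42), areas), 42)
  # two equal-area cells with densities 100 and 300 average to 200
  g1 <- grid_spec(30, c(0, 1, 0, 0.5))  # one row: equal areas
  expect_equal(
    mean_road_density(binary_layer(g1, 1),
                      density_layer(g1, c(100, 300)), cell_areas(g1)), 200)
  expect_error(mean_road_density(binary_layer(g, 0), density_layer(g, 1), areas),
               class = "roadrisk_validation_error")
})

test_that("mean density equals total road length over total range area", {
  # one straight meridional road of known geodesic length inside a rectangle
  g <- grid_spec(30, c(0, 2, 0, 2))
  areas <- cell_areas(g)
  road <- road_feature(cbind(c(0.75, 0.75), c(2, 0)), id = "r")
  dens <- line_density(road, g, areas)
  rng <- binary_layer(g, 1)
  L <- geosphere::distGeo(c(0.75, 2), c(0.75, 0))
  A <- sum(areas$values)
  expect_equal(mean_road_density(rng, dens, areas), L / A, tolerance = 1e-6)
})

test_that("unprotected fraction and road coverage are range-relative", {
  g <- grid_spec(30, c(0, 5, 0, 5))
  areas <- cell_areas(g)
  rng <- binary_layer(g, 1)
  expect_equal(unprotected_fraction(rng, binary_layer(g, 1), areas), 0)
  expect_equal(unprotected_fraction(rng, binary_layer(g, 0), areas), 1)
  # fosa-like fixture: 87 of 100 equal-area cells unprotected (one row band)
  g1 <- grid_spec(30, c(0, 50, 0, 0.5))
  pa <- binary_layer(g1, c(rep(0, 87), rep(1, 13)))
  expect_equal(unprotected_fraction(binary_layer(g1, 1), pa, cell_areas(g1)),
               0.87, tolerance = 1e-9)
  # coverage: density > 0 on 97 of 100 range cells
  d <- density_layer(g1, c(rep(10, 97), rep(0, 3)))
  expect_equal(road_coverage(binary_layer(g1, 1), d), 0.97)
  expect_equal(road_coverage(rng, density_layer(g, 0)), 0)
  expect_equal(road_coverage(rng, density_layer(g, 5)), 1)
  # nodata counts as uncovered
  dn <- density_layer(g1, c(rep(10, 97), rep(NA, 3)))
  expect_equal(road_coverage(binary_layer(g1, 1), dn), 0.97)
})

test_that("vulnerability is the stated weighted sum", {
  expect_equal(vulnerability(1, 1, 1, 1), 3)
  expect_equal(vulnerability(0, 0, 0, 0), 0)
  expect_equal(vulnerability(0.5, 1, 0, 0), 1.5)
  expect_error(vulnerability(1.2, 0, 0, 0), class = "roadrisk_validation_error")
})

test_that("risk table reproduces a direct evaluation of the risk equations", {
  st <- random_stack(101, n_species = 3)
  rt <- risk_table(st$traits, st$ranges, st$density, st$pa, st$areas)
  # recompute components independently
  dens <- vapply(st$traits$species, function(s) {
    w <- st$ranges[[s]]$values * st$areas$values
    d <- st$density$values; d[is.na(d)] <- 0
    sum(d * w) / sum(w)
  }, 0)
  npa <- vapply(st$traits$species, function(s) {
    w <- st$ranges[[s]]$values * st$areas$values
    sum(w * (1 - st$pa$values)) / sum(w)
  }, 0)
  iucn <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5)[st$traits$iucn_status]
  bm <- ifelse(st$traits$abm_kg > 100, 4, ifelse(st$traits$abm_kg >= 25, 3,
        ifelse(st$traits$abm_kg >= 15, 2, 1)))
  oracle <- risk_oracle(dens, npa, iucn, st$traits$n_threats, bm)
  expect_equal(rt$risk[match(st$traits$species, rt$species)],
               unname(oracle), tolerance = 1e-12)
})

test_that("single-species and ratio structure of the risk score", {
  st <- random_stack(7, n_species = 2)
  # single species: self-normalization gives risk 1
  rt1 <- risk_table(st$traits[1, ], st$ranges[1], st$density, st$pa, st$areas)
  expect_equal(rt1$exposure_star, 1)
  expect_equal(rt1$vulnerability_star, 1)
  expect_equal(rt1$risk, 1)
  # densities d and 4d with identical vulnerabilities -> risk ratio 0.5
  g1 <- grid_spec(60, c(0, 2, 0, 1))
  tr <- tibble::tibble(species = c("lo", "hi"), abm_kg = 50,
                       iucn_status = "VU", n_threats = 4)
  rl <- list(lo = binary_layer(g1, c(1, 0)),
             hi = binary_layer(g1, c(0, 1)))
  dd <- density_layer(g1, c(25, 100))
  rt <- risk_table(tr, rl, dd, binary_layer(g1, 0), cell_areas(g1))
  expect_equal(rt$risk[rt$species == "lo"] / rt$risk[rt$species == "hi"], 0.5)
})

test_that("risks are scale-invariant in density and monotone in components", {
  st <- random_stack(55, n_species = 6)
  rt <- risk_table(st$traits, st$ranges, st$density, st$pa, st$areas)
  # doubling all densities leaves risks unchanged
  d2 <- density_layer(st$grid, 2 * ifelse(is.na(st$density$values), 0,
                                          st$density$values))
  rt2 <- risk_table(st$traits, st$ranges, d2, st$pa, st$areas)
  expect_equal(rt2$risk, rt$risk, tolerance = 1e-12)
  # starred maxima are 1
  expect_equal(max(rt$exposure_star), 1)
  expect_equal(max(rt$vulnerability_star), 1)
  expect_true(all(rt$npa_star <= 1 & rt$iucn_star <= 1 &
                  rt$th_star <= 1 & rt$bm_star <= 1))
  # monotone: raising one species' threat count cannot lower its risk
  tr_up <- st$traits
  k <- which.min(tr_up$n_threats)
  sp <- tr_up$species[k]
  tr_up$n_threats[k] <- max(tr_up$n_threats) + 2
  rt3 <- risk_table(tr_up, st$ranges, st$density, st$pa, st$areas)
  expect_gte(rt3$risk[rt3$species == sp], rt$risk[rt$species == sp])
  # order invariance of the species rows
  perm <- sample(nrow(st$traits))
  rt4 <- risk_table(st$traits[perm, ], st$ranges, st$density, st$pa, st$areas)
  expect_equal(rt4, rt)
})

test_that("degenerate normalization raises an explicit error", {
  st <- random_stack(9, n_species = 2)
  zero <- density_layer(st$grid, 0)
  expect_error(risk_table(st$traits, st$ranges, zero, st$pa, st$areas),
               class = "roadrisk_normalization_error")
  tr0 <- st$traits; tr0$n_threats <- 0
  expect_error(risk_table(tr0, st$ranges, st$density, st$pa, st$areas),
               class = "roadrisk_normalization_error")
})

test_that("exposure ratio recovers sqrt of a constructed density ratio", {
  # species A's range density k times species B's, identical vulnerabilities
  for (k in c(2, 4, 9)) {
    g <- grid_spec(30, c(0, 4, 0, 2))
    areas <- cell_areas(g)
    # A: east half with k lines per column; B: west half with 1 line per column
    roads <- list()
    rid <- 0
    for (col in 1:8) {
      n <- if (col > 4) k else 1  # east half carries k lines per column
      for (j in seq_len(n)) {
        rid <- rid + 1
        lon <- (col - 1) * 0.5 + 0.5 * j / (n + 1)
        roads[[rid]] <- road_feature(cbind(c(lon, lon), c(2, 0)), id = rid)
      }
    }
    dens <- line_density(roads, g, areas)
    rngB <- binary_layer(g, {
      m <- matrix(0, g$nrow, g$ncol); m[, 1:4] <- 1; m })
    rngA <- binary_layer(g, {
      m <- matrix(0, g$nrow, g$ncol); m[, 5:8] <- 1; m })
    eA <- exposure(mean_road_density(rngA, dens, areas))
    eB <- exposure(mean_road_density(rngB, dens, areas))
    expect_equal(eA / eB, sqrt(k), tolerance = 0.01)
  }
})
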