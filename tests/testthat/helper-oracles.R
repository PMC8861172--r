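# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry code paths.

# point-in-polygon oracle backed by mgcv::in.out (boundary handling there is
# exclusive, so oracle comparisons use polygons whose edges avoid the test
# points)
pip_oracle <- function(lon, lat, rings) {
  bnd <- do.call(rbind, lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    if (i < length(rings)) rbind(r, c(NA, NA)) else r
  }))
  mgcv::in.out(bnd, cbind(lon, lat))
}

# densify-and-bin geodesic length oracle: chop every polyline segment into
# `n_sub` straight lon/lat pieces, credit each piece's geodesic length to the
# cell holding its midpoint
densify_bin_oracle <- function(coords, grid, n_sub = 400L) {
  out <- matrix(0, grid$nrow, grid$ncol)
  for (k in seq_len(nrow(coords) - 1L)) {
    a <- coords[k, ]; b <- coords[k + 1, ]
    t <- seq(0, 1, length.out = n_sub + 1L)
    px <- a[1] + t * (b[1] - a[1]); py <- a[2] + t * (b[2] - a[2])
    p0 <- cbind(px[-length(px)], py[-length(py)])
    p1 <- cbind(px[-1], py[-1])
    len <- geosphere::distGeo(p0, p1)
    mid <- (p0 + p1) / 2
    idx <- cell_index(grid, mid[, 1], mid[, 2])
    ok <- !is.na(idx[, "row"])
    for (j in which(ok))
      out[idx[j, "row"], idx[j, "col"]] <- out[idx[j, "row"], idx[j, "col"]] + len[j]
  }
  out
}

# simple axis-aligned rectangle polygon
rect_poly <- function(xmin, xmax, ymin, ymax, id = "r") {
  polygon_feature(rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                        c(xmin, ymax), c(xmin, ymin)), id = id)
}

# direct spreadsheet-style evaluation of the risk equations from raw
# components (independent of risk_table)
risk_oracle <- function(density, npa, iucn, th, bm) {
  expo <- sqrt(density)
  vul <- npa / max(npa) + iucn / max(iucn) + 0.5 * th / max(th) + 0.5 * bm / max(bm)
  (expo / max(expo)) * (vul / max(vul))
}

# small random multi-species stack for equation-fidelity checks
random_stack <- function(seed, n_species = 5, nrow = 12, ncol = 12) {
  set.seed(seed)
  g <- grid_spec(60, c(0, ncol, 0, nrow))
  areas <- cell_areas(g)
  dens <- density_layer(g, matrix(stats::rexp(nrow * ncol, 1 / 50) *
                                    stats::rbinom(nrow * ncol, 1, 0.7),
                                  nrow, ncol))
  pa <- binary_layer(g, matrix(stats::rbinom(nrow * ncol, 1, 0.3), nrow, ncol))
  ranges <- lapply(seq_len(n_species), function(i) {
    repeat {
      v <- matrix(stats::rbinom(nrow * ncol, 1, stats::runif(1, 0.2, 0.8)),
                  nrow, ncol)
      if (sum(v) > 0) return(binary_layer(g, v))
    }
  })
  names(ranges) <- sprintf("sp%02d", seq_len(n_species))
  traits <- tibble::tibble(
    species = names(ranges),
    abm_kg = stats::runif(n_species, 9, 200),
    iucn_status = sample(c("LC", "NT", "VU", "EN", "CR"), n_species, TRUE),
    n_threats = sample(1:10, n_species, TRUE))
  list(grid = g, areas = areas, density = dens, pa = pa, ranges = ranges,
       traits = traits)
}
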