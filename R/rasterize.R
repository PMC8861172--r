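#' Rasterize polygons to binary presence
#'
#' A cell scores 1 when its center lies inside (or on the boundary of) the
#' union of the input polygons — the deterministic cell-center rule. An
#' optional coverage-fraction mode scores 1 when at least `threshold` of a
#' `subsample` x `subsample` lattice of points inside the cell is covered
#' (an approximation to area coverage; the center rule remains the default).
#'
#' @param polygons polygon feature(s) in lon/lat degrees (see
#'   [polygon_feature()]).
#' @param grid a [grid_spec()].
#' @param rule `"center"` (default) or `"coverage"`.
#' @param threshold coverage fraction in (0, 1] for `rule = "coverage"`.
#' @param subsample points-per-side for the coverage lattice.
#' @return a `binary_layer`.
#' @export
rasterize_presence <- function(polygons, grid, rule = c("center", "coverage"),
                               threshold = 0.5, subsample = 4L) {
  rule <- match.arg(rule)
  if (is.null(polygons) || (is.list(polygons) && length(polygons) == 0 &&
                            !is.matrix(polygons))) {
    warn("empty polygon set: returning an all-zero presence layer.")
    return(binary_layer(grid, 0))
  }
  feats <- as_feature_list(polygons, "polygon_feature")
  ctr <- cell_centers(grid)
  vals <- matrix(0, grid$nrow, grid$ncol)
  if (rule == "center") {
    for (i in seq_len(grid$nrow)) {
      lat <- rep(ctr$lat[i], grid$ncol)
      vals[i, ] <- as.numeric(point_in_polygon(ctr$lon, lat, feats))
    }
  } else {
    off <- (seq_len(subsample) - 0.5) / subsample - 0.5
    for (i in seq_len(grid$nrow)) {
      hits <- matrix(0, 1, grid$ncol)
      for (dy in off) for (dx in off) {
        lon <- ctr$lon + dx * grid$res_deg
        lat <- rep(ctr$lat[i] + dy * grid$res_deg, grid$ncol)
        hits <- hits + as.numeric(point_in_polygon(lon, lat, feats))
      }
      vals[i, ] <- as.numeric(hits / subsample^2 >= threshold)
    }
  }
  binary_layer(grid, vals)
}

# split all polylines of a network at grid boundaries; one row per piece
split_lines_by_cell <- function(features, grid) {
  rows <- list()
  n <- 0L
  for (f in features) {
    coords <- f$coords
    if (any(coords[, 1] < grid$xmin - 1e-9 | coords[, 1] > grid$xmax + 1e-9 |
            coords[, 2] < grid$ymin - 1e-9 | coords[, 2] > grid$ymax + 1e-9))
      abort(sprintf("feature '%s' extends outside the grid extent.", f$id),
            class = "roadrisk_geometry_error")
    for (k in seq_len(nrow(coords) - 1L)) {
      a <- coords[k, ]; b <- coords[k + 1, ]
      ts <- grid_crossing_params(a, b, grid)
      for (piece in split_segment(a, b, ts)) {
        mid <- (piece$p + piece$q) / 2
        idx <- cell_index(grid, mid[1], mid[2])
        len <- geosphere::distGeo(piece$p, piece$q)
        if (len <= 0 || is.na(idx[1, "row"])) next
        n <- n + 1L
        rows[[n]] <- list(road_id = f$id, row = unname(idx[1, "row"]),
                          col = unname(idx[1, "col"]), length_m = len,
                          x0 = piece$p[1], y0 = piece$p[2],
                          x1 = piece$q[1], y1 = piece$q[2])
      }
    }
  }
  if (n == 0L)
    return(tibble::tibble(road_id = character(), row = integer(),
                          col = integer(), length_m = numeric(),
                          x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric()))
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Road density from polylines
#'
#' Splits every line exactly at cell boundaries (segments are straight in
#' lon/lat), measures each piece geodesically on the WGS84 ellipsoid, and
#' divides the total meters per cell by the cell area in km2 — the m/km2
#' density convention of gridded road inventories. Lines crossing the
#' antimeridian are rejected.
#'
#' @param polylines road feature(s) (see [road_feature()]) or coordinate
#'   matrices.
#' @param grid a [grid_spec()].
#' @param areas optional precomputed [cell_areas()] layer.
#' @return a `density_layer` (m/km2).
#' @export
line_density <- function(polylines, grid, areas = cell_areas(grid)) {
  stop_if_grid_mismatch(grid, areas$grid, "grid and area layer")
  feats <- if (is.null(polylines) || length(polylines) == 0) list()
           else as_feature_list(polylines, "road_feature")
  vals <- matrix(0, grid$nrow, grid$ncol)
  if (length(feats)) {
    pieces <- split_lines_by_cell(feats, grid)
    if (nrow(pieces)) {
      agg <- dplyr::summarise(dplyr::group_by(pieces, .data$row, .data$col),
                              length_m = sum(.data$length_m), .groups = "drop")
      vals[cbind(agg$row, agg$col)] <- agg$length_m
    }
  }
  density_layer(grid, vals / areas$values)
}
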