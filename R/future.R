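#' Split proposed roads at raster cell boundaries
#'
#' Each polyline is cut exactly where it crosses a grid meridian or
#' parallel; each piece is tagged with the (row, col) of the cell containing
#' its midpoint and measured geodesically. The pieces of one road partition
#' its geometry, so their lengths sum to the road length.
#'
#' @param network road feature(s) (see [road_feature()]).
#' @param grid a [grid_spec()].
#' @return tibble of segments: `road_id`, `cell_row`, `cell_col`,
#'   `length_km`, and the piece endpoints `x0, y0, x1, y1`.
#' @export
segment_by_cell <- function(network, grid) {
  feats <- as_feature_list(network, "road_feature")
  pieces <- split_lines_by_cell(feats, grid)
  tibble::tibble(road_id = pieces$road_id,
                 cell_row = pieces$row, cell_col = pieces$col,
                 length_km = pieces$length_m / 1000,
                 x0 = pieces$x0, y0 = pieces$y0,
                 x1 = pieces$x1, y1 = pieces$y1)
}

#' Assign cumulative risk and impact level to road segments
#'
#' Each segment inherits the cumulative road-risk value and the impact
#' level of the pixel it lies in; pixels with value 0 yield level 0.
#'
#' @param segments a [segment_by_cell()] tibble.
#' @param cumulative a `cumulative_risk_layer`.
#' @param levels an `impact_level_layer` on the same grid.
#' @return the segments tibble with `cum_risk` and `level` columns added.
#' @export
assign_impact <- function(segments, cumulative, levels) {
  stop_if_grid_mismatch(cumulative$grid, levels$grid,
                        "cumulative and level layers")
  idx <- cbind(segments$cell_row, segments$cell_col)
  segments$cum_risk <- cumulative$values[idx]
  segments$level <- levels$levels[idx]
  segments
}

#' Road length per impact level
#'
#' Kilometers and percentage of the total proposed-road length falling in
#' each impact level, including empty levels (reported as 0). Percentages
#' sum to 100.
#'
#' @param segments an impact-assigned segment tibble (see
#'   [assign_impact()]).
#' @param n_levels number of positive levels used (default 10).
#' @return tibble: `level` (0..n_levels), `length_km`, `pct`.
#' @export
level_length_distribution <- function(segments, n_levels = 10L) {
  if (nrow(segments) == 0)
    abort("no segments to summarize.", class = "roadrisk_validation_error")
  if (!"level" %in% names(segments))
    abort("segments carry no impact level; run assign_impact() first.",
          class = "roadrisk_validation_error")
  total <- sum(segments$length_km)
  lev <- seq.int(0L, n_levels)
  km <- vapply(lev, function(l) sum(segments$length_km[segments$level == l]), 0)
  tibble::tibble(level = lev, length_km = km, pct = 100 * km / total)
}

#' Proposed-road crossing lengths per species range
#'
#' Vector-on-vector overlay: the geodesic length of the proposed network
#' inside each species' range polygon, its share of the total network
#' length, and the crossing length relative to the species' total range
#' area (km of future road per km2 of distribution — the
#' future-road-length-to-range metric). Species with no overlap are
#' reported with zeros.
#'
#' @param network road feature(s).
#' @param range_polygons named list (by species) of polygon features.
#' @param range_area_km2 named numeric vector of range areas (km2), same
#'   names.
#' @return tibble: `species`, `crossing_km`, `pct_of_network`,
#'   `km_per_km2_range`, sorted by crossing length descending.
#' @export
species_crossing <- function(network, range_polygons, range_area_km2) {
  feats <- as_feature_list(network, "road_feature")
  total_km <- sum(vapply(feats, function(f) geodesic_length_m(f$coords), 0)) / 1000
  sp <- names(range_polygons)
  if (is.null(sp))
    abort("range_polygons must be a named list.", class = "roadrisk_validation_error")
  cross_km <- vapply(sp, function(s) {
    sum(vapply(feats, function(f)
      clip_length_m(f$coords, range_polygons[[s]]), 0)) / 1000
  }, 0)
  area <- range_area_km2[sp]
  tib <- tibble::tibble(
    species = sp,
    crossing_km = unname(cross_km),
    pct_of_network = 100 * unname(cross_km) / total_km,
    km_per_km2_range = unname(cross_km) / unname(area))
  dplyr::arrange(tib, dplyr::desc(.data$crossing_km), .data$species)
}

#' Protected areas intersected by proposed roads
#'
#' For every protected-area polygon: whether the network touches or crosses
#' it (direct intersection; a tangent single-point touch counts, with
#' length 0), the geodesic kilometers of network inside it, and whether it
#' lies within `buffer_km` of the network. Buffer membership is computed as
#' the minimum geodesic distance between the polygon and the network being
#' at most `buffer_km`, which is exactly membership in the geodesic buffer
#' of that width. Directly intersected PAs are by construction also within
#' any positive buffer. Features are deduplicated by id before counting.
#'
#' @param network road feature(s).
#' @param pa_polygons list of protected-area polygon features with stable
#'   ids.
#' @param buffer_km buffer distance in kilometers (default 10).
#' @return tibble: `pa_id`, `name`, `direct`, `length_km`,
#'   `within_buffer`, plus attributes `n_direct` and `n_buffered`.
#' @export
pa_intersections <- function(network, pa_polygons, buffer_km = 10) {
  if (buffer_km < 0)
    abort("buffer_km must be nonnegative.", class = "roadrisk_validation_error")
  net <- as_feature_list(network, "road_feature")
  pas <- as_feature_list(pa_polygons, "polygon_feature")
  ids <- vapply(pas, function(p) as.character(p$id), "")
  pas <- pas[!duplicated(ids)]
  rows <- lapply(pas, function(pa) {
    len_m <- sum(vapply(net, function(f) clip_length_m(f$coords, pa), 0))
    touches <- len_m > 0 ||
      any(vapply(net, function(f) {
        any(point_in_polygon(f$coords[, 1], f$coords[, 2], list(pa)))
      }, TRUE))
    dist_m <- if (touches) 0 else
      min(vapply(net, function(f)
        min_distance_line_polygon_m(f$coords, pa), 0))
    tibble::tibble(pa_id = as.character(pa$id),
                   name = if (is.null(pa$name)) NA_character_ else pa$name,
                   direct = touches,
                   length_km = len_m / 1000,
                   within_buffer = dist_m <= buffer_km * 1000)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_direct") <- sum(out$direct)
  attr(out, "n_buffered") <- sum(out$within_buffer)
  out
}
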