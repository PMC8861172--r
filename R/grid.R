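#' @importFrom stats setNames
#' @importFrom rlang abort warn .data
NULL

# Authalic sphere radius (km) used for cell areas; geodesic lengths elsewhere
# use the WGS84 ellipsoid via geosphere. The sub-percent inconsistency is
# deliberate and covered by test tolerances.
EARTH_RADIUS_KM <- 6371.0072

#' Define a geographic analysis grid
#'
#' Constructs the regular longitude/latitude lattice on which all raster
#' layers live. Cells are square in angular units. The grid is north-up:
#' row 1 touches the northern edge of the extent, column 1 the western edge.
#' Cell intervals are half-open, `[west, east) x (south, north]`, so every
#' point of the extent belongs to exactly one cell.
#'
#' @param resolution cell size in arc-minutes (default 5, roughly 9 km
#'   north-south at the equator).
#' @param extent numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in
#'   decimal degrees. Edges must be exact multiples of the resolution.
#'   Defaults to the whole globe.
#' @return an object of class `grid_spec` with fields `resolution`
#'   (arc-minutes), `res_deg`, `xmin`, `xmax`, `ymin`, `ymax`, `nrow`, `ncol`.
#' @examples
#' g <- grid_spec()            # 5-arcmin global grid: 2160 x 4320
#' g1 <- grid_spec(60)         # 1-degree global grid: 180 x 360
#' @export
grid_spec <- function(resolution = 5, extent = c(-180, 180, -90, 90)) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    abort("`resolution` must be a single positive number of arc-minutes.",
          class = "roadrisk_validation_error")
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4])
    abort("`extent` must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax.",
          class = "roadrisk_validation_error")
  if (extent[1] < -180 || extent[2] > 180 || extent[3] < -90 || extent[4] > 90)
    abort("`extent` must lie within [-180, 180] x [-90, 90].",
          class = "roadrisk_validation_error")
  res_deg <- resolution / 60
  snap <- function(x) abs(x / res_deg - round(x / res_deg)) < 1e-9
  if (!all(vapply(extent, snap, logical(1))))
    abort("extent edges must be exact multiples of the resolution (alignment error).",
          class = "roadrisk_alignment_error")
  structure(list(
    resolution = resolution,
    res_deg    = res_deg,
    xmin = extent[1], xmax = extent[2],
    ymin = extent[3], ymax = extent[4],
    nrow = as.integer(round((extent[4] - extent[3]) / res_deg)),
    ncol = as.integer(round((extent[2] - extent[1]) / res_deg))
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g arcmin, %d rows x %d cols, extent [%g, %g] x [%g, %g]\n",
              x$resolution, x$nrow, x$ncol, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("res_deg", "xmin", "xmax", "ymin", "ymax")],
                   unclass(b)[c("res_deg", "xmin", "xmax", "ymin", "ymax")]))
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!grid_equal(a, b))
    abort(sprintf("%s are on different grids (alignment error).", what),
          class = "roadrisk_alignment_error")
  invisible(TRUE)
}

#' Cell center coordinates
#'
#' Closed-form centers of grid cells. With no arguments returns the full
#' center lattice as a list of vectors.
#'
#' @param grid a [grid_spec()].
#' @param row,col optional 1-based indices (row 1 = northern edge).
#' @return if `row`/`col` given, a matrix with columns `lon`, `lat`;
#'   otherwise a list with vectors `lon` (length ncol) and `lat`
#'   (length nrow, decreasing).
#' @export
cell_centers <- function(grid, row = NULL, col = NULL) {
  lon_of <- function(j) grid$xmin + (j - 0.5) * grid$res_deg
  lat_of <- function(i) grid$ymax - (i - 0.5) * grid$res_deg
  if (is.null(row) && is.null(col))
    return(list(lon = lon_of(seq_len(grid$ncol)), lat = lat_of(seq_len(grid$nrow))))
  cbind(lon = lon_of(col), lat = lat_of(row))
}

#' Locate points on the grid
#'
#' Maps lon/lat points to 1-based (row, col) indices under the half-open
#' cell convention `[west, east) x (south, north]`. Points on the eastern or
#' southern extent edge are pulled into the last cell so the closed extent is
#' fully covered.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors in decimal degrees.
#' @return integer matrix with columns `row`, `col`; NA for points outside
#'   the extent.
#' @export
cell_index <- function(grid, lon, lat) {
  eps <- 1e-12
  col <- floor((lon - grid$xmin) / grid$res_deg) + 1L
  # (south, north]: a point exactly on a horizontal boundary belongs above
  row <- floor((grid$ymax - lat) / grid$res_deg) + 1L
  col[abs(lon - grid$xmax) <= eps] <- grid$ncol
  row[abs(lat - grid$ymin) <= eps] <- grid$nrow
  row[row < 1L | row > grid$nrow] <- NA_integer_
  col[col < 1L | col > grid$ncol] <- NA_integer_
  bad <- is.na(row) | is.na(col)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

new_layer <- function(grid, values, kind, nodata = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- matrix(values, nrow = grid$nrow, ncol = grid$ncol)
  structure(list(grid = grid, values = values, nodata = nodata),
            class = c(paste0(kind, "_layer"), "grid_layer"))
}

#' Construct raster layers on a grid
#'
#' `binary_layer()` holds 0/1 presence flags, `density_layer()` nonnegative
#' road densities in m/km2 (with an optional nodata mask stored as NA),
#' `count_layer()` nonnegative integers. Values are recycled to the grid
#' shape column-wise like [matrix()].
#'
#' @param grid a [grid_spec()].
#' @param values per-cell values (scalar or matrix/vector of length
#'   nrow*ncol).
#' @return a `grid_layer` with fields `grid`, `values` (matrix, row 1 =
#'   north) and `nodata`.
#' @export
binary_layer <- function(grid, values = 0) {
  v <- as.numeric(values)
  if (!all(v %in% c(0, 1)))
    abort("binary layer values must be 0 or 1.", class = "roadrisk_validation_error")
  new_layer(grid, v, "binary")
}

#' @rdname binary_layer
#' @export
density_layer <- function(grid, values = 0) {
  v <- as.numeric(values)
  if (any(v[!is.na(v)] < 0))
    abort("density values must be >= 0 (NA = nodata).",
          class = "roadrisk_validation_error")
  new_layer(grid, v, "density", nodata = NA_real_)
}

#' @rdname binary_layer
#' @export
count_layer <- function(grid, values = 0) {
  v <- as.numeric(values)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    abort("count values must be nonnegative integers.",
          class = "roadrisk_validation_error")
  new_layer(grid, v, "count")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<%s> on %d x %d grid; range [%g, %g]\n", class(x)[1],
              x$grid$nrow, x$grid$ncol,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Spherical cell areas
#'
#' Per-cell surface area in km2 on the authalic sphere (R = 6371.0072 km):
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`. Areas are constant
#' along rows and symmetric about the equator; summed over the global grid
#' they recover the sphere surface `4 pi R^2`.
#'
#' @param grid a [grid_spec()].
#' @return an `area_layer` (km2 per cell).
#' @export
cell_areas <- function(grid) {
  i <- seq_len(grid$nrow)
  lat_top <- grid$ymax - (i - 1) * grid$res_deg
  lat_bot <- grid$ymax - i * grid$res_deg
  dlam <- grid$res_deg * pi / 180
  row_area <- EARTH_RADIUS_KM^2 * dlam *
    (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  new_layer(grid, matrix(row_area, nrow = grid$nrow, ncol = grid$ncol),
            "area")
}

#' Aggregate road-type density layers
#'
#' Cellwise sum of density layers, e.g. the four non-local road types
#' (highways, primary, secondary, tertiary) of a gridded road inventory.
#' Local roads (type 5) carry a strong spatial bias toward developed
#' countries and should be excluded by the caller. Nodata (NA) counts as 0
#' wherever any sibling layer has data; a cell that is nodata in every layer
#' stays nodata.
#'
#' @param density_layers list of `density_layer`s on one grid.
#' @return a single `density_layer`.
#' @export
aggregate_road_types <- function(density_layers) {
  if (length(density_layers) == 0)
    abort("need at least one density layer.", class = "roadrisk_validation_error")
  g <- density_layers[[1]]$grid
  for (l in density_layers) stop_if_grid_mismatch(g, l$grid, "density layers")
  stack <- vapply(density_layers, function(l) l$values, density_layers[[1]]$values)
  dim(stack) <- c(g$nrow * g$ncol, length(density_layers))
  all_na <- rowSums(!is.na(stack)) == 0
  total <- rowSums(stack, na.rm = TRUE)
  total[all_na] <- NA_real_
  density_layer(g, matrix(total, g$nrow, g$ncol))
}

#' Species richness from presence layers
#'
#' Cellwise sum of binary presence layers: the number of species whose range
#' covers each cell.
#'
#' @param presence_layers list of `binary_layer`s on one grid.
#' @param grid required if `presence_layers` is empty (returns a zero layer).
#' @return a `count_layer`.
#' @export
richness <- function(presence_layers, grid = NULL) {
  if (length(presence_layers) == 0) {
    if (is.null(grid))
      abort("empty layer list: supply `grid` for the all-zero result.",
            class = "roadrisk_validation_error")
    return(count_layer(grid, 0))
  }
  g <- presence_layers[[1]]$grid
  total <- matrix(0, g$nrow, g$ncol)
  for (l in presence_layers) {
    stop_if_grid_mismatch(g, l$grid, "presence layers")
    total <- total + l$values
  }
  count_layer(g, total)
}
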