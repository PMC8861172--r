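#' Vector geometry containers
#'
#' Lightweight containers for the vector inputs of the pipeline. A *ring* is
#' a two-column lon/lat matrix (closed implicitly). A polygon feature is a
#' list of rings interpreted by the even-odd rule, so later rings punch
#' holes; a set of features is interpreted as their union. A road network is
#' a list of polyline features, each a lon/lat coordinate matrix with a
#' stable id.
#'
#' @param rings a ring matrix or list of ring matrices (lon, lat columns).
#' @param id stable feature identifier.
#' @param name optional display name.
#' @return `polygon_feature()` returns a classed list with `id`, `name`,
#'   `rings`; `road_feature()` one with `id`, `name`, `coords`.
#' @export
polygon_feature <- function(rings, id = NA, name = NULL) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, check_coords)
  structure(list(id = id, name = name, rings = rings), class = "polygon_feature")
}

#' @rdname polygon_feature
#' @param coords polyline vertex matrix (lon, lat).
#' @export
road_feature <- function(coords, id = NA, name = NULL) {
  structure(list(id = id, name = name, coords = check_coords(coords)),
            class = "road_feature")
}

check_coords <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2 || nrow(m) < 2 || any(!is.finite(m[, 1:2])))
    abort("coordinates must be a finite n x 2 lon/lat matrix with n >= 2.",
          class = "roadrisk_geometry_error")
  if (any(m[, 1] < -180 | m[, 1] > 180 | m[, 2] < -90 | m[, 2] > 90))
    abort("coordinates outside [-180,180] x [-90,90].",
          class = "roadrisk_geometry_error")
  if (any(abs(diff(m[, 1])) > 180))
    abort("geometry crosses the antimeridian; split it upstream.",
          class = "roadrisk_geometry_error")
  unname(m[, 1:2, drop = FALSE])
}

close_ring <- function(r) {
  if (any(r[1, ] != r[nrow(r), ])) rbind(r, r[1, ]) else r
}

as_feature_list <- function(x, kind) {
  if (inherits(x, kind)) return(list(x))
  if (is.matrix(x))
    return(list(if (kind == "polygon_feature") polygon_feature(x) else road_feature(x)))
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i) {
      f <- x[[i]]
      if (inherits(f, kind)) return(f)
      if (is.matrix(f))
        return(if (kind == "polygon_feature") polygon_feature(f, id = i)
               else road_feature(f, id = i))
      abort(sprintf("element %d is not a %s.", i, kind),
            class = "roadrisk_geometry_error")
    })
    return(out)
  }
  abort(sprintf("cannot interpret input as %s list.", kind),
        class = "roadrisk_geometry_error")
}

# --- point in polygon (even-odd ray casting, boundary-inclusive) -----------

pip_ring <- function(lon, lat, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(lon))
  onedge <- rep(FALSE, length(lon))
  eps <- 1e-12
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    # boundary test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- abs(cross) <= eps * max(1, sqrt(seglen2)) &
      lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    onedge <- onedge | on
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Point-in-polygon test
#'
#' Even-odd rule over a feature's rings (holes supported), boundary
#' inclusive; for a list of features, a point counts as inside the union if
#' it is inside any feature.
#'
#' @param lon,lat point coordinate vectors (degrees).
#' @param polygons a `polygon_feature`, a ring matrix, or a list of either.
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygons) {
  feats <- as_feature_list(polygons, "polygon_feature")
  res <- rep(FALSE, length(lon))
  for (f in feats) {
    inf <- rep(FALSE, length(lon))
    for (r in f$rings) inf <- xor(inf, pip_ring(lon, lat, r))
    # boundary-inclusive even-odd: re-check edges so hole boundaries count
    res <- res | inf
  }
  res
}

# --- geodesic measurement ---------------------------------------------------

#' Geodesic length of a polyline
#'
#' Sum of WGS84 geodesic distances between consecutive vertices.
#'
#' @param coords lon/lat vertex matrix.
#' @return length in meters.
#' @export
geodesic_length_m <- function(coords) {
  coords <- check_coords(coords)
  if (nrow(coords) < 2) return(0)
  sum(geosphere::distGeo(coords[-nrow(coords), , drop = FALSE],
                         coords[-1, , drop = FALSE]))
}

densify_coords <- function(coords, max_km = 1) {
  pieces <- list()
  for (k in seq_len(nrow(coords) - 1)) {
    a <- coords[k, ]; b <- coords[k + 1, ]
    d_km <- geosphere::distGeo(a, b) / 1000
    n <- max(1L, ceiling(d_km / max_km))
    t <- seq(0, 1, length.out = n + 1L)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    pieces[[k]] <- if (k > 1) seg[-1, , drop = FALSE] else seg
  }
  do.call(rbind, pieces)
}

# --- splitting a segment at parameter values -------------------------------

# parameters t in (0,1) where the lon/lat-straight segment crosses the grid's
# meridian/parallel lines
grid_crossing_params <- function(a, b, grid) {
  ts <- numeric(0)
  if (b[1] != a[1]) {
    ks <- seq(ceiling(min(a[1], b[1]) / grid$res_deg),
              floor(max(a[1], b[1]) / grid$res_deg))
    xs <- ks * grid$res_deg
    ts <- c(ts, (xs - a[1]) / (b[1] - a[1]))
  }
  if (b[2] != a[2]) {
    ks <- seq(ceiling(min(a[2], b[2]) / grid$res_deg),
              floor(max(a[2], b[2]) / grid$res_deg))
    ys <- ks * grid$res_deg
    ts <- c(ts, (ys - a[2]) / (b[2] - a[2]))
  }
  ts[ts > 1e-12 & ts < 1 - 1e-12]
}

# split one segment at sorted params; returns list of (p, q) sub-segments
split_segment <- function(a, b, ts) {
  ts <- sort(unique(c(0, ts, 1)))
  lapply(seq_len(length(ts) - 1L), function(i) {
    t0 <- ts[i]; t1 <- ts[i + 1]
    list(p = a + t0 * (b - a), q = a + t1 * (b - a))
  })
}

# intersection parameters of segment a-b (on the a-b parameterization) with
# the edges of polygon rings
polygon_crossing_params <- function(a, b, feats) {
  d <- b - a
  ts <- numeric(0)
  for (f in feats) for (ring in f$rings) {
    ring <- close_ring(ring)
    for (k in seq_len(nrow(ring) - 1L)) {
      c1 <- ring[k, ]; c2 <- ring[k + 1, ]
      e <- c2 - c1
      denom <- d[1] * e[2] - d[2] * e[1]
      if (abs(denom) < 1e-15) next  # parallel or collinear: boundary-running
      t <- ((c1[1] - a[1]) * e[2] - (c1[2] - a[2]) * e[1]) / denom
      u <- ((c1[1] - a[1]) * d[2] - (c1[2] - a[2]) * d[1]) / denom
      if (t > 1e-12 && t < 1 - 1e-12 && u >= -1e-12 && u <= 1 + 1e-12)
        ts <- c(ts, t)
    }
  }
  ts
}

#' Clip a polyline to a polygon union
#'
#' Splits every polyline segment (straight in lon/lat) at its crossings with
#' the polygon edges, classifies each piece by its midpoint, and sums the
#' WGS84 geodesic lengths of the pieces that fall inside.
#'
#' @param coords polyline vertex matrix.
#' @param polygons polygon feature(s) (union; even-odd holes honored).
#' @return length inside, in meters.
#' @export
clip_length_m <- function(coords, polygons) {
  coords <- check_coords(coords)
  feats <- as_feature_list(polygons, "polygon_feature")
  total <- 0
  for (k in seq_len(nrow(coords) - 1L)) {
    a <- coords[k, ]; b <- coords[k + 1, ]
    ts <- polygon_crossing_params(a, b, feats)
    for (piece in split_segment(a, b, ts)) {
      mid <- (piece$p + piece$q) / 2
      if (point_in_polygon(mid[1], mid[2], feats))
        total <- total + geosphere::distGeo(piece$p, piece$q)
    }
  }
  total
}

# minimum geodesic distance (m) between a polyline and a polygon boundary /
# interior; 0 when they touch or the line enters the polygon
min_distance_line_polygon_m <- function(coords, feat, densify_km = 2) {
  coords <- check_coords(coords)
  feats <- list(feat)
  dl <- densify_coords(coords, densify_km)
  if (any(point_in_polygon(dl[, 1], dl[, 2], feats))) return(0)
  best <- Inf
  for (ring in feat$rings) {
    ring_cl <- close_ring(ring)
    # polygon boundary vertices (densified) against the polyline ...
    bp <- densify_coords(ring_cl, densify_km)
    d1 <- suppressWarnings(geosphere::dist2Line(bp, coords))
    # ... and polyline vertices (densified) against the boundary
    d2 <- suppressWarnings(geosphere::dist2Line(dl, ring_cl))
    best <- min(best, min(d1[, "distance"]), min(d2[, "distance"]))
  }
  best
}
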