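#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster exchange. The header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) is validated against — or
#' used to build — a [grid_spec()]; nodata cells become NA.
#'
#' @param path file path (conventionally `.asc`).
#' @param layer a `grid_layer` to write.
#' @param nodata nodata sentinel written for NA cells.
#' @param kind layer class to construct on read: `"density"`, `"binary"` or
#'   `"count"`.
#' @return `read_ascii_grid()` returns a `grid_layer`; `write_ascii_grid()`
#'   the path, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  v <- layer$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", g$ncol),
           sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xmin),
           sprintf("yllcorner %.10g", g$ymin),
           sprintf("cellsize %.12g", g$res_deg),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 12),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, kind = c("density", "binary", "count")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  h <- setNames(vals, keys)
  res_deg <- h[["cellsize"]]
  nrow <- as.integer(h[["nrows"]]); ncol <- as.integer(h[["ncols"]])
  g <- grid_spec(res_deg * 60,
                 c(h[["xllcorner"]], h[["xllcorner"]] + ncol * res_deg,
                   h[["yllcorner"]], h[["yllcorner"]] + nrow * res_deg))
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nrow * ncol)
    abort(sprintf("raster body has %d values, expected %d.",
                  length(body), nrow * ncol),
          class = "roadrisk_validation_error")
  m <- matrix(body, nrow = nrow, ncol = ncol, byrow = TRUE)
  if ("nodata_value" %in% names(h)) m[m == h[["nodata_value"]]] <- NA
  switch(kind,
         density = density_layer(g, m),
         binary  = binary_layer(g, ifelse(is.na(m), 0, m)),
         count   = count_layer(g, ifelse(is.na(m), 0, m)))
}

# --- GeoJSON ---------------------------------------------------------------

geojson_geometry <- function(feat) {
  if (inherits(feat, "polygon_feature")) {
    list(type = "Polygon",
         coordinates = lapply(feat$rings, function(r) {
           r <- close_ring(r)
           lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
         }))
  } else {
    r <- feat$coords
    list(type = "LineString",
         coordinates = lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
  }
}

#' Read and write vector features as GeoJSON
#'
#' Supports Polygon/MultiPolygon (returned as [polygon_feature()] lists,
#' multipolygon parts flattened into one feature's ring list) and
#' LineString/MultiLineString (returned as [road_feature()] lists). Feature
#' ids are taken from the `id_field` property, falling back to the GeoJSON
#' `id` member, then to the feature index.
#'
#' @param features list of `polygon_feature`s or `road_feature`s.
#' @param path file path.
#' @param id_field property name holding the stable id (default `"id"`).
#' @return `read_geojson()` returns the feature list; `write_geojson()` the
#'   path, invisibly.
#' @export
write_geojson <- function(features, path) {
  features <- if (inherits(features, c("polygon_feature", "road_feature")))
    list(features) else features
  fc <- list(
    type = "FeatureCollection",
    features = lapply(features, function(f) {
      props <- list(id = f$id)
      if (!is.null(f$name)) props$name <- f$name
      list(type = "Feature", properties = props,
           geometry = geojson_geometry(f))
    }))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path, id_field = "id") {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    abort("expected a GeoJSON FeatureCollection.",
          class = "roadrisk_validation_error")
  coords_mat <- function(cc)
    do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  lapply(seq_along(fc$features), function(i) {
    ft <- fc$features[[i]]
    gm <- ft$geometry
    id <- ft$properties[[id_field]]
    if (is.null(id)) id <- ft$id
    if (is.null(id)) id <- i
    nm <- ft$properties$name
    switch(gm$type,
      Polygon = polygon_feature(lapply(gm$coordinates, coords_mat),
                                id = id, name = nm),
      MultiPolygon = polygon_feature(
        unlist(lapply(gm$coordinates, function(pg) lapply(pg, coords_mat)),
               recursive = FALSE), id = id, name = nm),
      LineString = road_feature(coords_mat(gm$coordinates), id = id, name = nm),
      MultiLineString = abort(
        "MultiLineString: split into one LineString feature per part.",
        class = "roadrisk_validation_error"),
      abort(sprintf("unsupported geometry type '%s'.", gm$type),
            class = "roadrisk_validation_error"))
  })
}
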