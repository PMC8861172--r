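#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with the fields: `density_rasters`
#' (named list or vector, one ASCII-grid path per road type, names
#' `type1`..`type5`), `included_types` (default 1-4; including type 5
#' triggers the spatial-bias warning and requires `force_type5: true`),
#' `ranges` (GeoJSON of species range polygons, feature id = species),
#' `pas` (GeoJSON of protected areas), `traits` (CSV), `wvc` (CSV,
#' optional), `future_roads` (GeoJSON, optional), `buffer_km` (default 10),
#' `n_levels` (default 10), `binning` (`equal`/`quantile`), `out_dir`.
#' Relative paths resolve against the config file's directory.
#'
#' @param path YAML config path.
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  cfg$density_rasters <- lapply(cfg$density_rasters, resolve)
  for (f in c("ranges", "pas", "traits", "wvc", "future_roads"))
    cfg[[f]] <- resolve(cfg[[f]])
  cfg$included_types <- if (is.null(cfg$included_types)) 1:4
                        else as.integer(cfg$included_types)
  cfg$buffer_km <- if (is.null(cfg$buffer_km)) 10 else cfg$buffer_km
  cfg$n_levels <- if (is.null(cfg$n_levels)) 10L else as.integer(cfg$n_levels)
  cfg$binning <- if (is.null(cfg$binning)) "equal" else cfg$binning
  cfg$out_dir <- if (is.null(cfg$out_dir)) file.path(base, "out")
                 else resolve(cfg$out_dir)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!all(cfg$included_types %in% 1:5))
    abort("included_types must be a subset of 1..5.",
          class = "roadrisk_validation_error")
  if (5L %in% cfg$included_types) {
    warn(paste("road type 5 (local roads) is spatially biased toward",
               "developed countries and is excluded by default."))
    if (!isTRUE(cfg$force_type5))
      cfg$included_types <- setdiff(cfg$included_types, 5L)
  }
  for (f in c("ranges", "traits")) {
    if (is.null(cfg[[f]]))
      abort(sprintf("config lacks required input '%s'.", f),
            class = "roadrisk_validation_error")
  }
  paths <- c(unlist(cfg$density_rasters),
             cfg$ranges, cfg$pas, cfg$traits, cfg$wvc, cfg$future_roads)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort(sprintf("input file(s) not found: %s.", paste(missing, collapse = ", ")),
          class = "roadrisk_validation_error")
  structure(cfg, class = "pipeline_config")
}

#' Run the full road-risk pipeline
#'
#' Executes the end-to-end analysis from a configuration: aggregate the
#' per-type road-density rasters (types 1-4 by default), rasterize species
#' ranges and protected areas, build the species risk table, the cumulative
#' risk surface and its impact levels, screen proposed roads when supplied
#' (segment impact, level length distribution, species crossings, PA
#' intersections with the buffer), and summarize WVC records when supplied.
#' All outputs land under `config$out_dir` with fixed names, together with
#' a `manifest.json` recording the configuration, input checksums and the
#' binning/buffer modes used.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or path
#'   to one.
#' @return invisibly, a list with the in-memory results: `risk`,
#'   `cumulative`, `levels`, and when inputs allow, `segments`,
#'   `level_table`, `crossings`, `pa_table`, `wvc_country`, `wvc_species`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "roadrisk_pipeline_error", parent = e))
  }

  dens_layers <- stage("density", {
    keys <- paste0("type", config$included_types)
    have <- intersect(keys, names(config$density_rasters))
    if (length(have) == 0)
      abort("no density raster for any included road type.")
    lapply(config$density_rasters[have], read_ascii_grid, kind = "density")
  })
  density <- stage("density", aggregate_road_types(unname(dens_layers)))
  grid <- density$grid
  areas <- cell_areas(grid)

  range_feats <- stage("rasterization", read_geojson(config$ranges))
  range_layers <- stage("rasterization", {
    ids <- vapply(range_feats, function(f) as.character(f$id), "")
    stats::setNames(lapply(range_feats, rasterize_presence, grid = grid), ids)
  })
  pa_layer <- stage("rasterization", {
    if (is.null(config$pas)) binary_layer(grid, 0)
    else rasterize_presence(read_geojson(config$pas), grid)
  })

  traits <- stage("risk", tibble::as_tibble(
    utils::read.csv(config$traits, stringsAsFactors = FALSE)))
  risk <- stage("risk",
                risk_table(traits, range_layers, density, pa_layer, areas))
  utils::write.csv(risk, out("risk_table.csv"), row.names = FALSE)

  cum <- stage("cumulative", cumulative_risk(risk, range_layers, pa_layer))
  lv <- stage("cumulative", impact_levels(cum, config$n_levels, config$binning))
  write_ascii_grid(new_layer(grid, cum$values, "density"),
                   out("cumulative_risk.asc"))
  write_ascii_grid(new_layer(grid, lv$levels, "count"),
                   out("impact_levels.asc"))

  res <- list(risk = risk, cumulative = cum, levels = lv)

  if (!is.null(config$future_roads)) {
    net <- stage("impact", read_geojson(config$future_roads))
    segs <- stage("impact", assign_impact(segment_by_cell(net, grid), cum, lv))
    res$segments <- segs
    res$level_table <- level_length_distribution(segs, config$n_levels)
    utils::write.csv(res$level_table, out("impact_levels_by_length.csv"),
                     row.names = FALSE)
    utils::write.csv(segs, out("segments.csv"), row.names = FALSE)
    rng_polys <- stats::setNames(range_feats,
                                 vapply(range_feats, function(f) as.character(f$id), ""))
    res$crossings <- species_crossing(
      net, rng_polys,
      stats::setNames(risk$range_area_km2, risk$species))
    utils::write.csv(res$crossings, out("species_crossings.csv"),
                     row.names = FALSE)
    if (!is.null(config$pas)) {
      res$pa_table <- pa_intersections(net, read_geojson(config$pas),
                                       buffer_km = config$buffer_km)
      utils::write.csv(res$pa_table, out("pa_intersections.csv"),
                       row.names = FALSE)
    }
  }

  if (!is.null(config$wvc)) {
    rec <- stage("wvc", read_wvc_csv(config$wvc))
    res$wvc_country <- wvc_country_summary(rec)
    res$wvc_species <- wvc_species_summary(rec, traits$species)
    utils::write.csv(res$wvc_country, out("wvc_country_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$wvc_species$table, out("wvc_species_summary.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    config = unclass(config),
    inputs = lapply(
      stats::setNames(nm = c(unlist(config$density_rasters), config$ranges,
                             config$pas, config$traits, config$wvc,
                             config$future_roads)),
      function(p) unname(tools::md5sum(p))),
    modes = list(binning = lv$mode, max_value = lv$max_value,
                 buffer_km = config$buffer_km,
                 rasterization = "cell-center",
                 included_types = config$included_types),
    generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(res)
}
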