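#' Parameters of a synthetic world
#'
#' Bundles every knob of the seeded generator. The default world is a
#' 36 x 36 cell half-degree window with 6 species, rectangular ranges
#' snapped to cell boundaries and a meridian-lattice road network, chosen so
#' that every derived quantity (range cell sets, per-cell road lengths,
#' densities, risk scores) has a closed-form ground truth. `range_mode =
#' "blob"` and `road_mode = "walk"` produce irregular geometries for
#' robustness fuzzing; those carry no closed-form sidecar and are meant to
#' be checked against brute-force oracles.
#'
#' @param resolution cell size in arc-minutes.
#' @param extent lon/lat bounding box, snapped to the resolution.
#' @param n_species number of species (>= 1).
#' @param range_mode `"rectangle"` or `"blob"`.
#' @param road_mode `"lattice"` (meridian lines of per-species intensity) or
#'   `"walk"` (random walks).
#' @param roads_per_species inclusive integer range of meridian lines (or
#'   walks) per species region.
#' @param pa_coverage target fraction of grid cells protected, in `[0, 1]`.
#' @param n_future_roads number of proposed-road polylines.
#' @param mass_range,threat_range trait sampling ranges (kg; count).
#' @param wvc_records_per_species inclusive range of WVC records generated
#'   per recorded species.
#' @param wvc_coverage fraction of species that get at least one WVC record.
#' @param seed integer seed; same parameters and seed give a byte-identical
#'   world.
#' @return a `world_params` list.
#' @export
world_params <- function(resolution = 30,
                         extent = c(0, 18, -9, 9),
                         n_species = 6,
                         range_mode = c("rectangle", "blob"),
                         road_mode = c("lattice", "walk"),
                         roads_per_species = c(2L, 12L),
                         pa_coverage = 0.25,
                         n_future_roads = 3L,
                         mass_range = c(5, 250),
                         threat_range = c(1L, 12L),
                         wvc_records_per_species = c(1L, 6L),
                         wvc_coverage = 0.8,
                         seed = 1L) {
  range_mode <- match.arg(range_mode)
  road_mode <- match.arg(road_mode)
  if (n_species < 1)
    abort("n_species must be >= 1.", class = "roadrisk_validation_error")
  if (pa_coverage < 0 || pa_coverage > 1 || wvc_coverage < 0 || wvc_coverage > 1)
    abort("coverage fractions must lie in [0, 1].",
          class = "roadrisk_validation_error")
  structure(list(resolution = resolution, extent = extent,
                 n_species = as.integer(n_species),
                 range_mode = range_mode, road_mode = road_mode,
                 roads_per_species = as.integer(roads_per_species),
                 pa_coverage = pa_coverage,
                 n_future_roads = as.integer(n_future_roads),
                 mass_range = mass_range,
                 threat_range = as.integer(threat_range),
                 wvc_records_per_species = as.integer(wvc_records_per_species),
                 wvc_coverage = wvc_coverage,
                 seed = as.integer(seed)),
            class = "world_params")
}

# meridian arc length (m) across one grid row, WGS84; independent of lon
row_arc_m <- function(grid, rows) {
  top <- grid$ymax - (rows - 1) * grid$res_deg
  bot <- grid$ymax - rows * grid$res_deg
  geosphere::distGeo(cbind(0, top), cbind(0, bot))
}

# spherical cell area per row (km2) — same closed form as cell_areas(), kept
# inline so ground truth carries its own arithmetic
row_area_km2 <- function(grid, rows) {
  top <- grid$ymax - (rows - 1) * grid$res_deg
  bot <- grid$ymax - rows * grid$res_deg
  EARTH_RADIUS_KM^2 * (grid$res_deg * pi / 180) *
    (sin(top * pi / 180) - sin(bot * pi / 180))
}

rect_polygon <- function(grid, r0, r1, c0, c1, id, name = NULL) {
  w <- grid$xmin + (c0 - 1) * grid$res_deg
  e <- grid$xmin + c1 * grid$res_deg
  n <- grid$ymax - (r0 - 1) * grid$res_deg
  s <- grid$ymax - r1 * grid$res_deg
  polygon_feature(rbind(c(w, s), c(e, s), c(e, n), c(w, n), c(w, s)),
                  id = id, name = name)
}

blob_polygon <- function(grid, id) {
  cx <- stats::runif(1, grid$xmin + 0.2 * (grid$xmax - grid$xmin),
                     grid$xmax - 0.2 * (grid$xmax - grid$xmin))
  cy <- stats::runif(1, grid$ymin + 0.2 * (grid$ymax - grid$ymin),
                     grid$ymax - 0.2 * (grid$ymax - grid$ymin))
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  rad <- stats::runif(1, 0.1, 0.18) * (grid$xmax - grid$xmin) *
    (1 + 0.3 * sin(3 * th + stats::runif(1, 0, 2 * pi)))
  ring <- cbind(pmin(pmax(cx + rad * cos(th), grid$xmin), grid$xmax),
                pmin(pmax(cy + rad * sin(th), grid$ymin), grid$ymax))
  polygon_feature(rbind(ring, ring[1, ]), id = id)
}

# a meridional road: one line at `lon`, spanning rows r0..r1 of the grid
meridian_road <- function(grid, lon, r0, r1, id) {
  top <- grid$ymax - (r0 - 1) * grid$res_deg
  bot <- grid$ymax - r1 * grid$res_deg
  road_feature(cbind(c(lon, lon), c(top, bot)), id = id)
}

walk_road <- function(grid, id, n_steps = 12) {
  step <- grid$res_deg * 1.5
  x <- stats::runif(1, grid$xmin + 2 * step, grid$xmax - 2 * step)
  y <- stats::runif(1, grid$ymin + 2 * step, grid$ymax - 2 * step)
  pts <- matrix(c(x, y), ncol = 2)
  ang <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(n_steps)) {
    ang <- ang + stats::rnorm(1, 0, 0.6)
    x <- min(max(x + step * cos(ang), grid$xmin), grid$xmax)
    y <- min(max(y + step * sin(ang), grid$ymin), grid$ymax)
    pts <- rbind(pts, c(x, y))
  }
  road_feature(pts, id = id)
}

#' Simulate a complete synthetic world
#'
#' Generates, from a single seed, every input the pipeline consumes —
#' species range polygons, a road network split into four road-type layers,
#' protected-area polygons, proposed-road polylines, a species trait table
#' and a WVC record table — plus, in rectangle/lattice mode, an analytic
#' ground-truth sidecar: exact range and PA cell sets, exact per-cell road
#' lengths (meridian arcs have closed-form geodesic lengths), expected
#' per-species density / unprotected fraction / coverage, and the expected
#' risk scores from a direct spreadsheet-style evaluation of the risk
#' equations, all computed without touching the pipeline's own code paths.
#'
#' @param params a [world_params()] object.
#' @param dir optional directory; when given, all inputs are written in the
#'   pipeline's external formats (GeoJSON, ASCII grid, CSV) together with
#'   the ground-truth sidecar (`ground_truth.csv` / `ground_truth.json`).
#' @return a `synthetic_world` list: `params`, `grid`, `range_polygons`,
#'   `road_features` (with a `road_type` attribute per feature),
#'   `pa_polygons`, `future_roads`, `traits`, `wvc`, `truth` (NULL outside
#'   rectangle/lattice mode), and `files` when `dir` was given.
#' @export
simulate_world <- function(params, dir = NULL) {
  stopifnot(inherits(params, "world_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(params$seed)

  grid <- grid_spec(params$resolution, params$extent)
  ns <- params$n_species
  species <- sprintf("Predator sp%02d", seq_len(ns))

  # --- ranges --------------------------------------------------------------
  closed_form <- params$range_mode == "rectangle" && params$road_mode == "lattice"
  range_rects <- vector("list", ns)
  range_polygons <- stats::setNames(vector("list", ns), species)
  min_side <- max(3L, floor(min(grid$nrow, grid$ncol) / 6))
  for (i in seq_len(ns)) {
    if (params$range_mode == "rectangle") {
      h <- sample(min_side:max(min_side, floor(grid$nrow / 2)), 1)
      w <- sample(min_side:max(min_side, floor(grid$ncol / 2)), 1)
      r0 <- sample(seq_len(grid$nrow - h + 1L), 1); r1 <- r0 + h - 1L
      c0 <- sample(seq_len(grid$ncol - w + 1L), 1); c1 <- c0 + w - 1L
      range_rects[[i]] <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
      range_polygons[[i]] <- rect_polygon(grid, r0, r1, c0, c1,
                                          id = species[i], name = species[i])
    } else {
      range_polygons[[i]] <- blob_polygon(grid, id = species[i])
    }
  }

  # --- roads (four types) --------------------------------------------------
  road_features <- list()
  road_types <- integer(0)
  # exact per-cell road length per type, accumulated analytically
  L <- lapply(1:4, function(t) matrix(0, grid$nrow, grid$ncol))
  rid <- 0L
  for (i in seq_len(ns)) {
    n_roads <- sample(params$roads_per_species[1]:params$roads_per_species[2], 1)
    if (n_roads == 0) next
    for (k in seq_len(n_roads)) {
      rid <- rid + 1L
      type <- sample(1:4, 1)
      if (params$road_mode == "lattice") {
        rc <- if (params$range_mode == "rectangle") range_rects[[i]] else
          c(r0 = 1L, r1 = grid$nrow, c0 = 1L, c1 = grid$ncol)
        col <- sample(rc["c0"]:rc["c1"], 1)
        # offset within the column keeps the line off cell boundaries
        lon <- grid$xmin + (col - 1L + stats::runif(1, 0.15, 0.85)) * grid$res_deg
        rd <- meridian_road(grid, lon, rc["r0"], rc["r1"], id = sprintf("road_%03d", rid))
        rows <- rc["r0"]:rc["r1"]
        L[[type]][cbind(rows, col)] <- L[[type]][cbind(rows, col)] + row_arc_m(grid, rows)
      } else {
        rd <- walk_road(grid, id = sprintf("road_%03d", rid))
      }
      attr(rd, "road_type") <- type
      road_features[[rid]] <- rd
      road_types[rid] <- type
    }
  }

  # --- protected areas -----------------------------------------------------
  pa_polygons <- list()
  pa_cells <- matrix(FALSE, grid$nrow, grid$ncol)
  if (params$pa_coverage > 0) {
    target <- params$pa_coverage * grid$nrow * grid$ncol
    j <- 0L
    while (sum(pa_cells) < target && j < 50L) {
      j <- j + 1L
      h <- sample(2:max(2, floor(grid$nrow / 3)), 1)
      w <- sample(2:max(2, floor(grid$ncol / 3)), 1)
      r0 <- sample(seq_len(grid$nrow - h + 1L), 1)
      c0 <- sample(seq_len(grid$ncol - w + 1L), 1)
      pa_polygons[[j]] <- rect_polygon(grid, r0, r0 + h - 1L, c0, c0 + w - 1L,
                                       id = sprintf("PA%03d", j))
      pa_cells[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
    }
  }

  # --- proposed roads ------------------------------------------------------
  future_roads <- lapply(seq_len(params$n_future_roads), function(k)
    walk_road(grid, id = sprintf("future_%02d", k), n_steps = 10))

  # --- traits --------------------------------------------------------------
  traits <- tibble::tibble(
    species = species,
    abm_kg = round(exp(stats::runif(ns, log(params$mass_range[1]),
                                    log(params$mass_range[2]))), 1),
    iucn_status = sample(c("LC", "NT", "VU", "EN", "CR"), ns, replace = TRUE),
    n_threats = sample(params$threat_range[1]:params$threat_range[2], ns,
                       replace = TRUE))

  # --- WVC records ---------------------------------------------------------
  n_rec_sp <- max(1L, round(params$wvc_coverage * ns))
  rec_sp <- sort(sample(seq_len(ns), n_rec_sp))
  countries <- c("Atlantis", "Borduria", "Costaguana", "Zubrowka")
  wvc_rows <- list()
  for (i in rec_sp) {
    n_rec <- sample(params$wvc_records_per_species[1]:params$wvc_records_per_species[2], 1)
    for (k in seq_len(n_rec)) {
      miss_ind <- stats::runif(1) < 0.15
      miss_yr <- stats::runif(1) < 0.15
      y0 <- sample(1963:2016, 1)
      dur <- sample(1:5, 1)
      wvc_rows[[length(wvc_rows) + 1L]] <- tibble::tibble(
        species = species[i],
        country = sample(countries, 1),
        individuals = if (miss_ind) NA_real_ else sample(1:40, 1),
        study_years = if (miss_yr) NA_real_ else dur,
        year_start = y0, year_end = y0 + dur - 1L,
        source_kind = sample(c("article", "report", "database", "thesis"), 1))
    }
  }
  wvc <- dplyr::bind_rows(wvc_rows)

  # --- analytic ground truth (rectangle/lattice only) ----------------------
  truth <- NULL
  if (closed_form) {
    area_cell <- matrix(row_area_km2(grid, seq_len(grid$nrow)),
                        grid$nrow, grid$ncol)
    L_total <- Reduce(`+`, L)
    truth_sp <- lapply(seq_len(ns), function(i) {
      rc <- range_rects[[i]]
      rows <- rc["r0"]:rc["r1"]; cols <- rc["c0"]:rc["c1"]
      a <- area_cell[rows, cols, drop = FALSE]
      l <- L_total[rows, cols, drop = FALSE]
      p <- pa_cells[rows, cols, drop = FALSE]
      list(range_rect = rc,
           area_km2 = sum(a),
           road_length_m = sum(l),
           density = sum(l) / sum(a),
           npa = sum(a[!p]) / sum(a),
           coverage = mean(l > 0))
    })
    if (any(vapply(truth_sp, function(t) t$area_km2, 0) <= 0))
      abort("parameter combination yields an empty range.",
            class = "roadrisk_validation_error")
    # direct evaluation of the risk equations, plain arithmetic
    dens <- vapply(truth_sp, function(t) t$density, 0)
    npa <- vapply(truth_sp, function(t) t$npa, 0)
    expo <- sqrt(dens)
    iucn <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5)[traits$iucn_status]
    bm <- ifelse(traits$abm_kg > 100, 4, ifelse(traits$abm_kg >= 25, 3,
          ifelse(traits$abm_kg >= 15, 2, 1)))
    th <- traits$n_threats
    vul <- npa / max(npa) + iucn / max(iucn) +
      0.5 * th / max(th) + 0.5 * bm / max(bm)
    risk <- (expo / max(expo)) * (vul / max(vul))
    truth <- list(
      per_species = tibble::tibble(
        species = species,
        area_km2 = vapply(truth_sp, function(t) t$area_km2, 0),
        road_length_m = vapply(truth_sp, function(t) t$road_length_m, 0),
        density = dens, npa = npa, coverage =
          vapply(truth_sp, function(t) t$coverage, 0),
        exposure = expo, vulnerability = unname(vul), risk = unname(risk)),
      range_rects = range_rects,
      road_length_by_type = L,
      pa_cells = pa_cells,
      area_cell = area_cell)
    # expected cumulative surface, direct per-cell evaluation
    ssr <- matrix(0, grid$nrow, grid$ncol)
    n_here <- matrix(0, grid$nrow, grid$ncol)
    for (i in seq_len(ns)) {
      rc <- range_rects[[i]]
      ssr[rc["r0"]:rc["r1"], rc["c0"]:rc["c1"]] <-
        ssr[rc["r0"]:rc["r1"], rc["c0"]:rc["c1"]] + risk[i]
      n_here[rc["r0"]:rc["r1"], rc["c0"]:rc["c1"]] <-
        n_here[rc["r0"]:rc["r1"], rc["c0"]:rc["c1"]] + 1
    }
    truth$cumulative <- ssr + ifelse(n_here > 0, ssr / pmax(n_here, 1), 0) * pa_cells
  }

  world <- structure(list(params = params, grid = grid,
                          range_polygons = range_polygons,
                          road_features = road_features,
                          road_types = road_types,
                          pa_polygons = pa_polygons,
                          future_roads = future_roads,
                          traits = traits, wvc = wvc, truth = truth),
                     class = "synthetic_world")
  if (!is.null(dir)) world$files <- write_world(world, dir)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d species, %d roads, %d PAs on a %d x %d grid (seed %d)\n",
              x$params$n_species, length(x$road_features),
              length(x$pa_polygons), x$grid$nrow, x$grid$ncol, x$params$seed))
  invisible(x)
}

# write every input file of the pipeline plus the ground-truth sidecar
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  files <- list()
  files$ranges <- write_geojson(unname(world$range_polygons), p("ranges.geojson"))
  if (length(world$pa_polygons))
    files$pas <- write_geojson(world$pa_polygons, p("pas.geojson"))
  if (length(world$road_features))
    files$roads <- write_geojson(world$road_features, p("roads.geojson"))
  files$future <- write_geojson(world$future_roads, p("future_roads.geojson"))
  utils::write.csv(world$traits, p("traits.csv"), row.names = FALSE)
  utils::write.csv(world$wvc, p("wvc.csv"), row.names = FALSE)
  # per-type density rasters (the road-inventory-style gridded input)
  areas <- cell_areas(world$grid)
  for (t in 1:4) {
    lay <- if (!is.null(world$truth)) {
      density_layer(world$grid, world$truth$road_length_by_type[[t]] / areas$values)
    } else {
      sel <- world$road_features[world$road_types == t]
      line_density(sel, world$grid, areas)
    }
    files[[paste0("density_type", t)]] <-
      write_ascii_grid(lay, p(sprintf("road_density_type%d.asc", t)))
  }
  if (!is.null(world$truth)) {
    utils::write.csv(world$truth$per_species, p("ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = world$params$seed,
           n_species = world$params$n_species,
           max_cumulative = max(world$truth$cumulative)),
      p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    files$ground_truth <- p("ground_truth.csv")
  }
  lapply(files, normalizePath)
}

#' A deterministic 36-species benchmark world
#'
#' Builds a fixed synthetic world with 36 species on non-overlapping block
#' ranges whose road densities decrease along a constructed gradient: the
#' top species has roads through about 97% of its range cells and the
#' highest density, the runner-up about two thirds of that density, and the
#' last species a road-free boreal-like range. Trait values reinforce the
#' same ordering, so the expected risk ranking is known by construction and
#' an independent direct evaluation of the risk equations ships in `truth`.
#'
#' @return a `synthetic_world` whose `truth$per_species` table carries the
#'   constructed expected ranking.
#' @export
make_benchmark_world <- function() {
  grid <- grid_spec(30, c(0, 18, -9, 9))  # 36 x 36 cells
  ns <- 36L
  species <- sprintf("Fixture predator %02d", seq_len(ns))
  block <- 6L
  range_rects <- vector("list", ns)
  range_polygons <- stats::setNames(vector("list", ns), species)
  road_features <- list()
  road_types <- integer(0)
  L <- lapply(1:4, function(t) matrix(0, grid$nrow, grid$ncol))
  rid <- 0L
  # lines per species: strictly decreasing intensity, last species roadless
  n_lines <- round(seq(18, 0, length.out = ns))
  # density ratio of species 2 to species 1 targets ~2/3 via line counts
  n_lines[2] <- max(1, round(n_lines[1] * 2 / 3))
  for (i in seq_len(ns)) {
    bi <- (i - 1L) %/% 6L; bj <- (i - 1L) %% 6L
    r0 <- bi * block + 1L; r1 <- r0 + block - 1L
    c0 <- bj * block + 1L; c1 <- c0 + block - 1L
    range_rects[[i]] <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
    range_polygons[[i]] <- rect_polygon(grid, r0, r1, c0, c1,
                                        id = species[i], name = species[i])
    if (n_lines[i] == 0) next
    # species 1: its last column gets exactly one line that stops one row
    # short, leaving a single roadless cell (35 of 36 covered)
    cols <- if (i == 1L) c(c1, rep(c0:(c1 - 1L), length.out = n_lines[i] - 1L))
            else rep(c0:c1, length.out = n_lines[i])
    for (k in seq_len(n_lines[i])) {
      rid <- rid + 1L
      col <- cols[k]
      lon <- grid$xmin + (col - 1L + 0.2 + 0.6 * (k - 1) / max(1, n_lines[i])) *
        grid$res_deg
      rows <- r0:r1
      if (i == 1L && k == 1L) rows <- r0:(r1 - 1L)  # leaves one cell roadless
      rd <- meridian_road(grid, lon, rows[1], rows[length(rows)],
                          id = sprintf("fix_road_%03d", rid))
      type <- ((rid - 1L) %% 4L) + 1L
      attr(rd, "road_type") <- type
      road_features[[rid]] <- rd
      road_types[rid] <- type
      L[[type]][cbind(rows, col)] <- L[[type]][cbind(rows, col)] +
        row_arc_m(grid, rows)
    }
  }
  # PAs: protect two block ranges fully and a horizontal band
  pa_polygons <- list(
    rect_polygon(grid, 31L, 36L, 31L, 36L, id = "PA001"),  # species 36 block
    rect_polygon(grid, 25L, 30L, 25L, 30L, id = "PA002"),
    rect_polygon(grid, 13L, 15L, 1L, 36L, id = "PA003"))
  pa_cells <- matrix(FALSE, grid$nrow, grid$ncol)
  pa_cells[31:36, 31:36] <- TRUE
  pa_cells[25:30, 25:30] <- TRUE
  pa_cells[13:15, 1:36] <- TRUE

  # traits reinforcing the constructed gradient
  grad <- (ns - seq_len(ns)) / (ns - 1)        # 1 for species 1, 0 for last
  traits <- tibble::tibble(
    species = species,
    abm_kg = round(8 + 120 * grad, 1),
    iucn_status = c("CR", "EN", "VU", "NT", "LC")[pmin(5L, ceiling(seq_len(ns) / 8L))],
    n_threats = pmax(1L, round(12 * grad)))

  # WVC: records for 30 of the 36 species
  rec_sp <- seq_len(30L)
  wvc <- dplyr::bind_rows(lapply(rec_sp, function(i) tibble::tibble(
    species = species[i], country = c("Atlantis", "Borduria")[1 + i %% 2],
    individuals = 3 + (i %% 7), study_years = 1 + (i %% 4),
    year_start = 1990 + i, year_end = 1990 + i + (i %% 4),
    source_kind = "article")))

  future_roads <- list(road_feature(cbind(c(0.2, 17.8), c(-8.6, 8.6)),
                                    id = "future_diag"))

  # direct evaluation of the risk equations (ground truth)
  area_cell <- matrix(row_area_km2(grid, seq_len(grid$nrow)), grid$nrow, grid$ncol)
  L_total <- Reduce(`+`, L)
  per <- lapply(seq_len(ns), function(i) {
    rc <- range_rects[[i]]
    rows <- rc["r0"]:rc["r1"]; cols <- rc["c0"]:rc["c1"]
    a <- area_cell[rows, cols]; l <- L_total[rows, cols]
    p <- pa_cells[rows, cols]
    c(area = sum(a), len = sum(l), dens = sum(l) / sum(a),
      npa = sum(a[!p]) / sum(a), cov = mean(l > 0))
  })
  dens <- vapply(per, `[[`, 0, "dens")
  npa <- vapply(per, `[[`, 0, "npa")
  expo <- sqrt(dens)
  iucn <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5)[traits$iucn_status]
  bm <- ifelse(traits$abm_kg > 100, 4, ifelse(traits$abm_kg >= 25, 3,
        ifelse(traits$abm_kg >= 15, 2, 1)))
  vul <- npa / max(npa) + iucn / max(iucn) +
    0.5 * traits$n_threats / max(traits$n_threats) + 0.5 * bm / max(bm)
  risk <- (expo / max(expo)) * (vul / max(vul))
  truth <- list(
    per_species = tibble::tibble(
      species = species,
      area_km2 = vapply(per, `[[`, 0, "area"),
      road_length_m = vapply(per, `[[`, 0, "len"),
      density = dens, npa = npa,
      coverage = vapply(per, `[[`, 0, "cov"),
      exposure = expo, vulnerability = unname(vul), risk = unname(risk)),
    range_rects = range_rects,
    road_length_by_type = L,
    pa_cells = pa_cells,
    area_cell = area_cell)

  structure(list(params = NULL, grid = grid,
                 range_polygons = range_polygons,
                 road_features = road_features, road_types = road_types,
                 pa_polygons = pa_polygons, future_roads = future_roads,
                 traits = traits, wvc = wvc, truth = truth),
            class = "synthetic_world")
}
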