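#' Body-mass category of a predator
#'
#' Ordinal body-mass class used in the vulnerability score, a proxy for home
#' range size: very large (> 100 kg) = 4, large (25-100 kg) = 3, medium
#' (15-25 kg) = 2, small (8-15 kg) = 1. The printed class ranges share
#' endpoints; classes are taken lower-inclusive/upper-exclusive with the top
#' of each range joining the class above, i.e. `[8,15) -> 1`, `[15,25) -> 2`,
#' `[25,100] -> 3`, `> 100 -> 4`. Masses below 8 kg (ecosystem-level apex
#' predators under the size threshold) fall into class 1 with a warning.
#'
#' @param abm_kg average body mass in kilograms (vectorized).
#' @return integer categories 1-4.
#' @export
body_mass_category <- function(abm_kg) {
  if (any(!is.finite(abm_kg)) || any(abm_kg <= 0))
    abort("body mass must be positive.", class = "roadrisk_validation_error")
  if (any(abm_kg < 8))
    warn("body mass below 8 kg: assigned to the smallest class (1).")
  ifelse(abm_kg > 100, 4L,
  ifelse(abm_kg >= 25, 3L,
  ifelse(abm_kg >= 15, 2L, 1L)))
}

#' IUCN status value
#'
#' Ordinal conservation-status value: LC = 1, NT = 2, VU = 3, EN = 4,
#' CR = 5.
#'
#' @param status character vector of Red List codes.
#' @return integer values 1-5.
#' @export
iucn_value <- function(status) {
  scale <- c(LC = 1L, NT = 2L, VU = 3L, EN = 4L, CR = 5L)
  v <- scale[toupper(trimws(status))]
  if (any(is.na(v)))
    abort(sprintf("unknown IUCN status code(s): %s.",
                  paste(unique(status[is.na(v)]), collapse = ", ")),
          class = "roadrisk_validation_error")
  unname(v)
}

#' Road exposure from density
#'
#' The exposure term of the risk score: the square root of the mean road
#' density (m/km2) within a species' range.
#'
#' @param road_density mean density in m/km2 (vectorized, >= 0).
#' @return `sqrt(road_density)`.
#' @export
exposure <- function(road_density) {
  if (any(road_density < 0, na.rm = TRUE))
    abort("road density must be >= 0.", class = "roadrisk_validation_error")
  sqrt(road_density)
}

range_area_weights <- function(range_layer, areas) {
  stop_if_grid_mismatch(range_layer$grid, areas$grid, "range and area layers")
  w <- range_layer$values * areas$values
  if (sum(w) <= 0)
    abort("species range is empty on this grid.",
          class = "roadrisk_validation_error")
  w
}

#' Mean road density over a species range
#'
#' Area-weighted mean of the density layer over the range cells, which
#' equals total road length (m) within the range divided by total range
#' area (km2). Nodata density cells count as 0 road.
#'
#' @param range_layer `binary_layer` of the species range.
#' @param density_layer `density_layer` (m/km2).
#' @param areas [cell_areas()] layer.
#' @return mean density in m/km2.
#' @export
mean_road_density <- function(range_layer, density_layer, areas) {
  stop_if_grid_mismatch(range_layer$grid, density_layer$grid,
                        "range and density layers")
  w <- range_area_weights(range_layer, areas)
  d <- density_layer$values
  d[is.na(d)] <- 0
  sum(d * w) / sum(w)
}

#' Fraction of a range outside protected areas
#'
#' Area of range cells not flagged as protected, divided by total range
#' area.
#'
#' @inheritParams mean_road_density
#' @param pa_layer `binary_layer` of protected-area cells.
#' @return nPA in `[0, 1]`.
#' @export
unprotected_fraction <- function(range_layer, pa_layer, areas) {
  stop_if_grid_mismatch(range_layer$grid, pa_layer$grid,
                        "range and protected-area layers")
  w <- range_area_weights(range_layer, areas)
  sum(w * (1 - pa_layer$values)) / sum(w)
}

#' Road coverage of a range
#'
#' Fraction of range cells with strictly positive road density (nodata
#' counts as uncovered). Cell-count based, matching the "share of the
#' distribution covered by roads" descriptive statistic.
#'
#' @inheritParams mean_road_density
#' @return fraction in `[0, 1]`.
#' @export
road_coverage <- function(range_layer, density_layer) {
  stop_if_grid_mismatch(range_layer$grid, density_layer$grid,
                        "range and density layers")
  n_range <- sum(range_layer$values)
  if (n_range == 0)
    abort("species range is empty on this grid.",
          class = "roadrisk_validation_error")
  d <- density_layer$values
  covered <- !is.na(d) & d > 0
  sum(covered & range_layer$values > 0) / n_range
}

#' Species vulnerability score
#'
#' Weighted sum of the four max-normalized vulnerability components:
#' `nPA* + IUCN* + 0.5 TH* + 0.5 BM*`. Unprotected range fraction and IUCN
#' status carry full weight; threat count and body-mass class half weight.
#'
#' @param npa_star,iucn_star,th_star,bm_star components in `[0, 1]`
#'   (vectorized).
#' @return vulnerability in `[0, 3]`.
#' @export
vulnerability <- function(npa_star, iucn_star, th_star, bm_star) {
  comp <- cbind(npa_star, iucn_star, th_star, bm_star)
  if (any(comp < 0 | comp > 1))
    abort("all normalized components must lie in [0, 1].",
          class = "roadrisk_validation_error")
  npa_star + iucn_star + 0.5 * th_star + 0.5 * bm_star
}

max_normalize <- function(x, what) {
  m <- max(x)
  if (!is.finite(m) || m <= 0)
    abort(sprintf("degenerate normalization: maximum %s over the species set is %s.",
                  what, format(m)),
          class = "roadrisk_normalization_error")
  x / m
}

#' Species road-risk table
#'
#' Computes the full per-species risk assessment: mean road density over the
#' range, exposure (its square root), the four vulnerability components
#' (unprotected fraction, IUCN value, threat count, body-mass class), the
#' max-normalized starred versions of each, vulnerability, and the final
#' road risk — the product of max-normalized exposure and max-normalized
#' vulnerability. Every maximum is taken over the analyzed species set, so
#' the species set itself is part of the model input: adding or removing a
#' species rescales all risks.
#'
#' @param traits data frame with columns `species`, `abm_kg`, `iucn_status`,
#'   `n_threats`, and optionally `bm_category` (overrides the class derived
#'   from `abm_kg`).
#' @param range_layers named list of `binary_layer`s, one per species; names
#'   must match `traits$species`.
#' @param density_layer aggregated road `density_layer`.
#' @param pa_layer protected-area `binary_layer`.
#' @param areas [cell_areas()] layer.
#' @return tibble with one row per species (columns: species, road_density,
#'   exposure_raw, npa, iucn_value, th_count, bm_category, npa_star,
#'   iucn_star, th_star, bm_star, vulnerability_raw, exposure_star,
#'   vulnerability_star, risk, road_coverage, range_area_km2), sorted by
#'   risk descending, ties alphabetical.
#' @export
risk_table <- function(traits, range_layers, density_layer, pa_layer, areas) {
  traits <- tibble::as_tibble(traits)
  req <- c("species", "abm_kg", "iucn_status", "n_threats")
  miss <- setdiff(req, names(traits))
  if (length(miss))
    abort(sprintf("traits table lacks column(s): %s.", paste(miss, collapse = ", ")),
          class = "roadrisk_validation_error")
  sp <- traits$species
  if (anyDuplicated(sp))
    abort("duplicate species in traits table.", class = "roadrisk_validation_error")
  absent <- setdiff(sp, names(range_layers))
  if (length(absent))
    abort(sprintf("no range layer for species: %s.", paste(absent, collapse = ", ")),
          class = "roadrisk_validation_error")
  if (any(traits$n_threats < 0))
    abort("n_threats must be nonnegative.", class = "roadrisk_validation_error")

  dens <- vapply(sp, function(s)
    mean_road_density(range_layers[[s]], density_layer, areas), 0)
  npa <- vapply(sp, function(s)
    unprotected_fraction(range_layers[[s]], pa_layer, areas), 0)
  cov <- vapply(sp, function(s)
    road_coverage(range_layers[[s]], density_layer), 0)
  area <- vapply(sp, function(s)
    sum(range_layers[[s]]$values * areas$values), 0)

  bm <- if ("bm_category" %in% names(traits) && any(!is.na(traits$bm_category))) {
    override <- traits$bm_category
    derived <- body_mass_category(traits$abm_kg)
    ifelse(is.na(override), derived, as.integer(override))
  } else body_mass_category(traits$abm_kg)
  iucn <- iucn_value(traits$iucn_status)
  th <- as.numeric(traits$n_threats)

  out <- tibble::tibble(
    species = sp,
    road_density = unname(dens),
    exposure_raw = exposure(unname(dens)),
    npa = unname(npa),
    iucn_value = iucn,
    th_count = th,
    bm_category = as.integer(bm),
    npa_star  = max_normalize(unname(npa), "unprotected fraction"),
    iucn_star = max_normalize(iucn, "IUCN value"),
    th_star   = max_normalize(th, "threat count"),
    bm_star   = max_normalize(as.numeric(bm), "body-mass category"))
  out$vulnerability_raw <- vulnerability(out$npa_star, out$iucn_star,
                                         out$th_star, out$bm_star)
  out$exposure_star <- max_normalize(out$exposure_raw, "road exposure")
  out$vulnerability_star <- max_normalize(out$vulnerability_raw, "vulnerability")
  out$risk <- out$exposure_star * out$vulnerability_star
  out$road_coverage <- unname(cov)
  out$range_area_km2 <- unname(area)
  dplyr::arrange(out, dplyr::desc(.data$risk), .data$species)
}
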