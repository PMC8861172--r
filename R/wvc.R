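#' Normalize wildlife-vehicle-collision records
#'
#' Applies the database's imputation convention to a raw record table:
#' missing counts of road-killed individuals and missing study durations are
#' both assumed to be one, species and country strings are trimmed, and
#' species binomials are canonicalized (first word capitalized, rest lower
#' case) for case-insensitive matching. Records with calendar years outside
#' the observed 1963-2021 span are flagged, not rejected.
#'
#' @param records data frame with columns `species`, `country`,
#'   `individuals`, `study_years` and optionally `year_start`, `year_end`,
#'   `source_kind`. Blank cells are missing.
#' @return a tibble with the same rows, normalized columns, an
#'   `annual_rate` column (individuals per year) and a logical
#'   `year_flagged` column.
#' @export
normalize_wvc <- function(records) {
  rec <- tibble::as_tibble(records)
  needed <- c("species", "country")
  for (col in needed)
    if (!col %in% names(rec))
      abort(sprintf("WVC table lacks required column '%s'.", col),
            class = "roadrisk_validation_error")
  bad <- which(is.na(rec$species) | trimws(rec$species) == "" |
               is.na(rec$country) | trimws(rec$country) == "")
  if (length(bad))
    abort(sprintf("WVC rows with missing species/country: %s.",
                  paste(bad, collapse = ", ")),
          class = "roadrisk_validation_error")
  if (!"individuals" %in% names(rec)) rec$individuals <- NA_real_
  if (!"study_years" %in% names(rec)) rec$study_years <- NA_real_
  rec$species <- canonical_binomial(rec$species)
  rec$country <- trimws(rec$country)
  rec$individuals <- ifelse(is.na(rec$individuals), 1, as.numeric(rec$individuals))
  rec$study_years <- ifelse(is.na(rec$study_years), 1, as.numeric(rec$study_years))
  if (any(rec$individuals < 0) || any(rec$study_years <= 0))
    abort("individuals must be >= 0 and study_years > 0.",
          class = "roadrisk_validation_error")
  rec$annual_rate <- rec$individuals / rec$study_years
  ys <- if ("year_start" %in% names(rec)) rec$year_start else NA_real_
  ye <- if ("year_end" %in% names(rec)) rec$year_end else NA_real_
  if (any(!is.na(ys) & !is.na(ye) & ys > ye))
    abort("year_start exceeds year_end in some rows.",
          class = "roadrisk_validation_error")
  rec$year_flagged <- (!is.na(ys) & ys < 1963) | (!is.na(ye) & ye > 2021)
  rec
}

canonical_binomial <- function(x) {
  x <- tolower(trimws(gsub("\\s+", " ", x)))
  sub("^(\\w)", "\\U\\1", x, perl = TRUE)
}

#' Annual roadkill rate of a record
#'
#' Individuals killed per year: the count of road-killed individuals divided
#' by the study duration in years. Vectorized.
#'
#' @param individuals nonnegative counts.
#' @param study_years positive durations (years).
#' @return numeric vector of rates.
#' @export
annual_rate <- function(individuals, study_years) {
  if (any(study_years <= 0))
    abort("study_years must be positive.", class = "roadrisk_validation_error")
  individuals / study_years
}

#' Per-country WVC summary
#'
#' For each country: the single-year WVC total (sum over that country's
#' records of their annual rates, i.e. each study contributes its per-year
#' kill rate) and the sampling effort (sum of study durations in years).
#' With `per_year_max = TRUE` the single-year total is instead the largest
#' annual rate among the country's records (experimental alternative
#' reading).
#'
#' @param records a normalized WVC tibble (see [normalize_wvc()]).
#' @param per_year_max use the max-rate convention instead of sum-of-rates.
#' @return tibble with `country`, `wvc_single_year`, `effort_years`,
#'   `n_records`, sorted by country.
#' @export
wvc_country_summary <- function(records, per_year_max = FALSE) {
  rec <- normalize_wvc(records)
  if (nrow(rec) == 0)
    return(tibble::tibble(country = character(), wvc_single_year = numeric(),
                          effort_years = numeric(), n_records = integer()))
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$country),
    wvc_single_year = if (per_year_max) max(.data$annual_rate)
                      else sum(.data$annual_rate),
    effort_years = sum(.data$study_years),
    n_records = dplyr::n(),
    .groups = "drop")
  dplyr::arrange(out, .data$country)
}

#' Per-species WVC summary and coverage
#'
#' For each species: total individuals, record count, and the largest
#' single-study annual rate. Coverage counts how many species of the
#' analyzed universe have at least one record. Records naming species
#' outside the universe are retained and flagged.
#'
#' @param records a WVC record table (normalized internally).
#' @param species_universe character vector of analyzed species binomials.
#' @return list with `table` (tibble: species, total_individuals,
#'   n_records, max_annual_rate, in_universe) and `coverage` (integer).
#' @export
wvc_species_summary <- function(records, species_universe) {
  rec <- normalize_wvc(records)
  uni <- canonical_binomial(species_universe)
  if (nrow(rec) == 0)
    return(list(table = tibble::tibble(species = character(),
                                       total_individuals = numeric(),
                                       n_records = integer(),
                                       max_annual_rate = numeric(),
                                       in_universe = logical()),
                coverage = 0L))
  tab <- dplyr::summarise(
    dplyr::group_by(rec, .data$species),
    total_individuals = sum(.data$individuals),
    n_records = dplyr::n(),
    max_annual_rate = max(.data$annual_rate),
    .groups = "drop")
  tab$in_universe <- tab$species %in% uni
  if (any(!tab$in_universe))
    warn(sprintf("records for %d species outside the analyzed universe.",
                 sum(!tab$in_universe)))
  list(table = dplyr::arrange(tab, dplyr::desc(.data$total_individuals)),
       coverage = sum(uni %in% tab$species))
}

#' Read a WVC record CSV
#'
#' Schema (one row per study x species x country): `species`, `country`,
#' `individuals`, `study_years`, `year_start`, `year_end`, `source_kind`.
#' Blank cells are treated as missing and normalized per [normalize_wvc()].
#'
#' @param path CSV path.
#' @return a normalized WVC tibble.
#' @export
read_wvc_csv <- function(path) {
  normalize_wvc(utils::read.csv(path, stringsAsFactors = FALSE,
                                na.strings = c("", "NA")))
}
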