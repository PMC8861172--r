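#' Cumulative road-risk surface
#'
#' Per-pixel aggregation of the species risk scores with a protected-area
#' term: `value = SSR + beta * PA`, where SSR is the sum of the risks of
#' the species whose ranges cover the pixel, beta the mean risk of those
#' species (0 where no species is present, a stated convention), and PA the
#' binary protected flag. On a protected pixel with n species present the
#' value therefore equals `SSR * (1 + 1/n)`.
#'
#' @param risk a [risk_table()] tibble (or any data frame with `species` and
#'   `risk` columns).
#' @param range_layers named list of `binary_layer`s covering every species
#'   in `risk` that should contribute; every layer's name must appear in
#'   `risk$species`.
#' @param pa_layer protected-area `binary_layer`.
#' @return object of class `cumulative_risk_layer`: list with `grid`, `ssr`,
#'   `n_species`, `beta`, `pa`, `values` (all matrices except grid).
#' @export
cumulative_risk <- function(risk, range_layers, pa_layer) {
  if (length(range_layers) == 0)
    abort("need at least one range layer.", class = "roadrisk_validation_error")
  sp <- names(range_layers)
  if (is.null(sp) || any(sp == ""))
    abort("range_layers must be a named list (species names).",
          class = "roadrisk_validation_error")
  missing_sp <- setdiff(sp, risk$species)
  if (length(missing_sp))
    abort(sprintf("species missing from the risk table: %s.",
                  paste(missing_sp, collapse = ", ")),
          class = "roadrisk_validation_error")
  g <- range_layers[[1]]$grid
  stop_if_grid_mismatch(g, pa_layer$grid, "range and protected-area layers")
  ssr <- matrix(0, g$nrow, g$ncol)
  n <- matrix(0, g$nrow, g$ncol)
  for (s in sp) {
    l <- range_layers[[s]]
    stop_if_grid_mismatch(g, l$grid, "range layers")
    r <- risk$risk[match(s, risk$species)]
    ssr <- ssr + r * l$values
    n <- n + l$values
  }
  beta <- ifelse(n > 0, ssr / pmax(n, 1), 0)
  vals <- ssr + beta * pa_layer$values
  structure(list(grid = g, ssr = ssr, n_species = n, beta = beta,
                 pa = pa_layer$values, values = vals),
            class = "cumulative_risk_layer")
}

#' @export
print.cumulative_risk_layer <- function(x, ...) {
  cat(sprintf("<cumulative_risk_layer> %d x %d; max %.4g; %d occupied cells\n",
              x$grid$nrow, x$grid$ncol, max(x$values), sum(x$n_species > 0)))
  invisible(x)
}

#' Discretize cumulative risk into impact levels
#'
#' Maps the continuous cumulative-risk surface to integer impact levels
#' 1..n_levels; cells with value 0 (no species present and unprotected) get
#' level 0. The default is equal-width bins over `(0, max]` with ceiling
#' assignment — `level = ceiling(n_levels * value / max)` — so the
#' maximum-attaining cells land exactly on the top level; `"quantile"` bins
#' the positive values by their empirical quantiles instead. The normalizing
#' maximum should come from the full analysis extent so levels are
#' comparable across regional windows; pass `max_value` to impose it.
#'
#' @param cumulative a `cumulative_risk_layer`.
#' @param n_levels number of positive levels (default 10).
#' @param mode `"equal"` (default) or `"quantile"`.
#' @param max_value optional externally supplied normalizing maximum.
#' @return object of class `impact_level_layer`: list with `grid`, `levels`
#'   (integer matrix), `n_levels`, `mode`, `max_value`.
#' @export
impact_levels <- function(cumulative, n_levels = 10L,
                          mode = c("equal", "quantile"), max_value = NULL) {
  mode <- match.arg(mode)
  v <- cumulative$values
  pos <- v > 0
  if (!any(pos))
    abort("cumulative layer is identically zero; no levels to assign.",
          class = "roadrisk_validation_error")
  m <- if (is.null(max_value)) max(v) else max_value
  lv <- matrix(0L, nrow(v), ncol(v))
  if (mode == "equal") {
    lv[pos] <- pmin(pmax(ceiling(n_levels * v[pos] / m), 1L), n_levels)
  } else {
    br <- stats::quantile(v[pos], probs = seq(0, 1, length.out = n_levels + 1))
    br[1] <- 0; br[n_levels + 1] <- max(m, max(v))
    lv[pos] <- as.integer(cut(v[pos], breaks = unique(br),
                              labels = FALSE, include.lowest = TRUE))
    lv[pos] <- pmin(lv[pos], n_levels)
  }
  structure(list(grid = cumulative$grid, levels = lv,
                 n_levels = as.integer(n_levels), mode = mode, max_value = m),
            class = "impact_level_layer")
}
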