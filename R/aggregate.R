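#' Inclusive linear-interpolation percentile
#'
#' The spreadsheet percentile convention: for sorted values `v[1..n]` the
#' rank position is `h = 1 + p * (n - 1)` and the result interpolates
#' linearly between `v[floor(h)]` and `v[floor(h) + 1]`, so `p = 0` returns
#' the minimum and `p = 1` the maximum exactly. Equivalent to
#' `stats::quantile(type = 7)`.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability in `[0, 1]`.
#' @return The interpolated percentile.
#' @examples
#' percentile(c(1, 2, 3, 4, 5), 0.25)  # 2
#' percentile(c(0, 10), 0.75)          # 7.5
#' @export
percentile <- function(values, p) {
  if (!length(values)) {
    abort("percentile() needs a non-empty input.", class = "basinrank_domain_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("percentile() requires finite values.", class = "basinrank_domain_error")
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1].", class = "basinrank_domain_error")
  }
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Base-10 log transform with a half-minimum floor for zeros
#'
#' Positive values map to `log10(x)`. Zeros map to `log10` of half the
#' smallest positive value in the input, so zero-concentration subbasins stay
#' rankable (strictly below every observed value) without infinities. An
#' all-zero input is returned unchanged with a warning, since no positive
#' floor exists.
#'
#' @param values Non-negative numeric vector.
#' @return Transformed vector of the same length.
#' @export
log10_floored <- function(values) {
  if (anyNA(values) || any(!is.finite(values))) {
    abort("log10_floored() requires finite values.", class = "basinrank_domain_error")
  }
  if (any(values < 0)) {
    abort("log10_floored() is undefined for negative values.",
          class = "basinrank_domain_error")
  }
  pos <- values > 0
  if (!any(pos)) {
    warn("log10_floored(): all values are zero; returning them untransformed.")
    return(values)
  }
  floor_val <- log10(min(values[pos]) / 2)
  out <- ifelse(pos, log10(pmax(values, .Machine$double.xmin)), floor_val)
  as.numeric(out)
}

#' Collapse subbasin values to one basin-level value
#'
#' Applies the spec'd transform to each subbasin value, then the aggregation
#' statistic: `median`, `iqr_range` (75th minus 25th percentile of the HUC08
#' values, an outlier-resistant spread measure), `minimum`, or `mean_abs`
#' (mean absolute value, for signed model residuals).
#'
#' @param sub_values Non-empty numeric vector of subbasin values.
#' @param spec A [variable_spec()] with a subbasin aggregation.
#' @return A single numeric value.
#' @examples
#' sp <- variable_spec("x_range", "factor", "x", aggregation = "iqr_range")
#' aggregate_variable(c(1, 2, 3, 4, 5), sp)  # 2
#' @export
aggregate_variable <- function(sub_values, spec) {
  if (!length(sub_values)) {
    abort(sprintf("No subbasin values to aggregate for '%s'.", spec$name),
          class = "basinrank_domain_error")
  }
  x <- switch(spec$transform,
              none = as.numeric(sub_values),
              log10_floored = log10_floored(sub_values))
  switch(spec$aggregation,
         median = percentile(x, 0.5),
         iqr_range = percentile(x, 0.75) - percentile(x, 0.25),
         minimum = min(x),
         mean_abs = mean(abs(x)),
         abort(sprintf("Aggregation '%s' is not a subbasin statistic.", spec$aggregation),
               class = "basinrank_config_error"))
}

#' Delivered yield from a total delivered load
#'
#' Normalizes the annual nutrient load a basin delivers to its distant
#' receiving water by basin area, giving kg/km\eqn{^2}/yr.
#'
#' @param total_delivered_load Load in kg/yr.
#' @param area_km2 Basin area in km\eqn{^2}; must be positive.
#' @return Yield in kg/km\eqn{^2}/yr.
#' @export
delivered_yield <- function(total_delivered_load, area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    abort("`area_km2` must be positive.", class = "basinrank_domain_error")
  }
  total_delivered_load / area_km2
}

#' Build the basin-by-variable table for one configuration
#'
#' Evaluates every variable specification against the basin and subbasin
#' tables: basin-level variables are taken directly (or divided by basin area
#' for `sum_over_area`); subbasin-level variables are transformed and
#' aggregated per basin. For median-type subbasin variables (e.g., basin
#' groundwater nitrate), a pre-aggregated basin-level column of the same
#' `source_column` name in the basins table takes precedence when present,
#' with a message; spread statistics always come from the subbasin values.
#'
#' @param basins,subbasins Validated tables (see [validate_tables()]).
#' @param config A [ranking_config()].
#' @return A tibble with `basin_id`, `region_id`, and one numeric column per
#'   variable name, plus a `provenance` attribute recording, per variable,
#'   the subbasin count used and the transform applied.
#' @export
build_variable_table <- function(basins, subbasins, config) {
  v <- validate_tables(basins, subbasins)
  basins <- v$basins; subbasins <- v$subbasins
  sub_split <- split(subbasins, factor(subbasins$basin_id, levels = basins$basin_id))
  n_sub <- vapply(sub_split, nrow, integer(1))

  out <- tibble::tibble(basin_id = basins$basin_id, region_id = basins$region_id)
  prov <- list()
  for (spec in config$variables) {
    use_basin_col <- spec$level == "basin" ||
      (spec$aggregation == "median" && spec$source_column %in% names(basins))
    if (use_basin_col) {
      if (!spec$source_column %in% names(basins)) {
        abort(sprintf("basins table lacks column '%s' needed by variable '%s'.",
                      spec$source_column, spec$name), class = "basinrank_schema_error")
      }
      if (spec$level == "subbasin") {
        inform(sprintf("Using pre-aggregated basin-level column '%s' for variable '%s'.",
                       spec$source_column, spec$name))
      }
      raw <- basins[[spec$source_column]]
      val <- if (spec$aggregation == "sum_over_area") {
        delivered_yield(raw, basins$area_km2)
      } else raw
      if (identical(spec$transform, "log10_floored")) val <- log10_floored(val)
      out[[spec$name]] <- as.numeric(val)
      prov[[spec$name]] <- list(n_subbasins = rep(1L, nrow(basins)),
                                transform = spec$transform)
    } else {
      if (!spec$source_column %in% names(subbasins)) {
        abort(sprintf("subbasins table lacks column '%s' needed by variable '%s'.",
                      spec$source_column, spec$name), class = "basinrank_schema_error")
      }
      vals <- vapply(sub_split, function(df) {
        x <- df[[spec$source_column]]
        x <- x[!is.na(x)]
        if (!length(x)) return(NA_real_)
        aggregate_variable(x, spec)
      }, numeric(1))
      if (spec$aggregation == "iqr_range" && any(n_sub == 1L)) {
        warn(sprintf("Variable '%s': %d basin(s) have a single subbasin; their range is 0.",
                     spec$name, sum(n_sub == 1L)))
      }
      out[[spec$name]] <- unname(vals)
      prov[[spec$name]] <- list(n_subbasins = unname(n_sub), transform = spec$transform)
    }
  }
  attr(out, "provenance") <- prov
  out
}
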