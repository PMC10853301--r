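#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median quantile rbeta rgamma rlnorm rnorm runif sd cor
NULL

# Controlled vocabularies shared across the package
.br_categories   <- c("water_quality", "source", "factor", "receptor", "accuracy")
.br_levels       <- c("basin", "subbasin")
.br_aggregations <- c("median", "iqr_range", "minimum", "mean_abs", "sum_over_area", "none")
.br_transforms   <- c("none", "log10_floored")
.br_directions   <- c("ascending", "descending")

#' Define a scored variable
#'
#' A variable specification describes one column of the basin or subbasin
#' table that enters a ranking approach: which category it scores, how
#' subbasin values are collapsed to a single basin value, whether values are
#' log-transformed first, which direction counts as favorable, and its weight
#' inside the category score.
#'
#' @param name Identifier for the derived basin-level variable.
#' @param category Scoring category, one of `"water_quality"`, `"source"`,
#'   `"factor"`, `"receptor"`, `"accuracy"`.
#' @param source_column Column name in the basin or subbasin table holding the
#'   raw values.
#' @param level `"basin"` (one value per basin) or `"subbasin"` (one value per
#'   HUC08, collapsed by `aggregation`).
#' @param aggregation How subbasin values are collapsed: `"median"`,
#'   `"iqr_range"` (75th minus 25th percentile), `"minimum"`, `"mean_abs"`
#'   (mean absolute value, used for model residuals), `"sum_over_area"`
#'   (basin-level total divided by basin area), or `"none"` (basin-level
#'   value used as is).
#' @param transform `"none"` or `"log10_floored"` (base-10 log with zeros
#'   floored to half the smallest positive value), applied to each value
#'   before aggregation.
#' @param direction `"ascending"` if larger raw values are more favorable
#'   (rank closer to 1), `"descending"` otherwise.
#' @param weight Positive weighting factor inside the category score.
#'
#' @return An object of class `variable_spec`.
#' @examples
#' variable_spec("stream_N_median", "water_quality", "stream_N_vwm",
#'               level = "subbasin", aggregation = "median")
#' @export
variable_spec <- function(name, category, source_column,
                          level = c("subbasin", "basin"),
                          aggregation = "median",
                          transform = "none",
                          direction = "ascending",
                          weight = 1) {
  level <- match.arg(level)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "basinrank_config_error")
  }
  if (!category %in% .br_categories) {
    abort(sprintf("Unknown category '%s' for variable '%s' (expected one of %s).",
                  category, name, paste(.br_categories, collapse = ", ")),
          class = "basinrank_config_error")
  }
  if (!aggregation %in% .br_aggregations) {
    abort(sprintf("Unknown aggregation '%s' for variable '%s'.", aggregation, name),
          class = "basinrank_config_error")
  }
  if (!transform %in% .br_transforms) {
    abort(sprintf("Unknown transform '%s' for variable '%s'.", transform, name),
          class = "basinrank_config_error")
  }
  if (!direction %in% .br_directions) {
    abort(sprintf("Unknown direction '%s' for variable '%s'.", direction, name),
          class = "basinrank_config_error")
  }
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0) {
    abort(sprintf("Variable '%s' must have a finite weight > 0.", name),
          class = "basinrank_config_error")
  }
  if (level == "subbasin" && aggregation == "none") {
    abort(sprintf("Subbasin-level variable '%s' needs an aggregation other than 'none'.", name),
          class = "basinrank_config_error")
  }
  if (level == "basin" && !aggregation %in% c("none", "sum_over_area")) {
    abort(sprintf("Basin-level variable '%s' must use aggregation 'none' or 'sum_over_area'.", name),
          class = "basinrank_config_error")
  }
  structure(
    list(name = name, category = category, source_column = source_column,
         level = level, aggregation = aggregation, transform = transform,
         direction = direction, weight = as.numeric(weight)),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s [%s] %s(%s:%s) %s w=%g\n",
              x$name, x$category, x$aggregation, x$level, x$source_column,
              x$direction, x$weight))
  invisible(x)
}

#' @export
format.variable_spec <- function(x, ...) {
  sprintf("%s [%s] w=%g", x$name, x$category, x$weight)
}
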