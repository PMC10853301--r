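#' Assemble and validate a ranking configuration
#'
#' A ranking configuration bundles the ordered variable specifications for one
#' approach together with category-level weights, the category normalization
#' convention, and the eligibility-penalty settings used by the variability
#' approach.
#'
#' The impact approach carries exactly 14 variables in three categories
#' (water quality, source, receptor), each category normalized by its variable
#' count and weighted 1.0 in the overall score. The variability approach
#' carries exactly 20 variables in four categories (water quality, factor,
#' accuracy, receptor), each normalized by its total weight, with the receptor
#' and accuracy categories down-weighted to 0.5 and an eligibility rule that
#' subtracts 5 points from the water-quality score of any basin outside its
#' region's top four water-quality scores.
#'
#' @param approach `"impact"` or `"variability"`.
#' @param variables List of [variable_spec()] objects.
#' @param category_weights Named numeric vector of weights for the overall
#'   score, one entry per category present among `variables`.
#' @param category_normalization `"by_variable_count"` (divide the weighted
#'   rank sum by the number of variables in the category) or `"by_weight_sum"`
#'   (divide by the category's total weight so every category spans `[0, 1]`).
#' @param eligibility List with elements `enabled` (flag), `top_k` (integer),
#'   `penalty` (points subtracted from the water-quality score), and `scope`
#'   (`"region"`). Only meaningful for the variability approach.
#'
#' @return An object of class `ranking_config`.
#' @seealso [default_config()], [load_config()]
#' @export
ranking_config <- function(approach,
                           variables,
                           category_weights,
                           category_normalization = c("by_variable_count", "by_weight_sum"),
                           eligibility = list(enabled = FALSE, top_k = 4L,
                                              penalty = 5, scope = "region")) {
  category_normalization <- match.arg(category_normalization)
  if (!approach %in% c("impact", "variability")) {
    abort(sprintf("Unknown approach '%s'.", approach), class = "basinrank_config_error")
  }
  if (!is.list(variables) || !length(variables) ||
      !all(vapply(variables, inherits, logical(1), "variable_spec"))) {
    abort("`variables` must be a non-empty list of variable_spec objects.",
          class = "basinrank_config_error")
  }
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(names(variables))) {
    abort("Variable names must be unique.", class = "basinrank_config_error")
  }
  n_expected <- c(impact = 14L, variability = 20L)[[approach]]
  if (length(variables) != n_expected) {
    abort(sprintf("The %s approach requires exactly %d variables (got %d).",
                  approach, n_expected, length(variables)),
          class = "basinrank_config_error")
  }
  cats <- unique(vapply(variables, `[[`, character(1), "category"))
  if (!is.numeric(category_weights) || is.null(names(category_weights))) {
    abort("`category_weights` must be a named numeric vector.",
          class = "basinrank_config_error")
  }
  extra <- setdiff(names(category_weights), cats)
  if (length(extra)) {
    abort(sprintf("category_weights name categories absent from the variables: %s.",
                  paste(extra, collapse = ", ")), class = "basinrank_config_error")
  }
  missing_w <- setdiff(cats, names(category_weights))
  if (length(missing_w)) {
    abort(sprintf("Missing category weight for: %s.", paste(missing_w, collapse = ", ")),
          class = "basinrank_config_error")
  }
  eligibility <- utils::modifyList(
    list(enabled = FALSE, top_k = 4L, penalty = 5, scope = "region"), eligibility)
  if (isTRUE(eligibility$enabled) && approach != "variability") {
    abort("The eligibility penalty is only defined for the variability approach.",
          class = "basinrank_config_error")
  }
  if (eligibility$top_k < 1 || eligibility$penalty < 0) {
    abort("eligibility needs top_k >= 1 and penalty >= 0.",
          class = "basinrank_config_error")
  }
  structure(
    list(approach = approach,
         variables = variables,
         category_weights = category_weights[cats],
         category_normalization = category_normalization,
         eligibility = eligibility),
    class = "ranking_config"
  )
}

#' @export
print.ranking_config <- function(x, ...) {
  cats <- vapply(x$variables, `[[`, character(1), "category")
  cat(sprintf("<ranking_config> approach: %s, %d variables, normalization: %s\n",
              x$approach, length(x$variables), x$category_normalization))
  for (ct in unique(cats)) {
    cat(sprintf("  %s (weight %.2g): %s\n", ct, x$category_weights[[ct]],
                paste(names(x$variables)[cats == ct], collapse = ", ")))
  }
  if (isTRUE(x$eligibility$enabled)) {
    cat(sprintf("  eligibility: top-%d water-quality, penalty %.3g, scope %s\n",
                x$eligibility$top_k, x$eligibility$penalty, x$eligibility$scope))
  }
  invisible(x)
}

#' Load a ranking configuration from a YAML document
#'
#' Reads one approach configuration (see the shipped documents under
#' `system.file("extdata/config", package = "basinrank")` for the schema) and
#' validates it against the approach invariants.
#'
#' @param path Path to a YAML configuration.
#' @param approach Expected approach; defaults to the one named in the file.
#' @return A validated [ranking_config()].
#' @export
load_config <- function(path, approach = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "basinrank_io_error")
  }
  doc <- yaml::read_yaml(path)
  approach <- approach %||% doc$approach
  if (!identical(doc$approach, approach)) {
    abort(sprintf("Config declares approach '%s' but '%s' was requested.",
                  doc$approach, approach), class = "basinrank_config_error")
  }
  vars <- lapply(doc$variables, function(v) {
    variable_spec(name = v$name, category = v$category,
                  source_column = v$source_column, level = v$level,
                  aggregation = v$aggregation %||% "none",
                  transform = v$transform %||% "none",
                  direction = v$direction %||% "ascending",
                  weight = v$weight %||% 1)
  })
  elig <- doc$eligibility %||% list(enabled = FALSE)
  ranking_config(
    approach = approach,
    variables = vars,
    category_weights = unlist(doc$category_weights),
    category_normalization = doc$category_normalization,
    eligibility = elig
  )
}

#' Default approach configurations
#'
#' Returns the shipped configuration for one of the two ranking approaches:
#' 14 variables for the impact approach and 20 for the variability approach,
#' with the published weighting factors (for example 1.5 on shallow
#' groundwater nitrate, 0.5 on nitrate at public-supply depth, and 0.5 on
#' delivered nitrogen and phosphorus yields).
#'
#' @param approach `"impact"` or `"variability"`.
#' @return A [ranking_config()].
#' @examples
#' default_config("impact")
#' @export
default_config <- function(approach = c("impact", "variability")) {
  approach <- match.arg(approach)
  path <- system.file("extdata", "config", paste0(approach, ".yaml"),
                      package = "basinrank", mustWork = TRUE)
  load_config(path, approach)
}
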