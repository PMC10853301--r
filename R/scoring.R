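#' Percent-rank normalization with spreadsheet tie handling
#'
#' Maps each value to the fraction of the other values it strictly exceeds:
#' `rank(x) = #(values < x) / (n - 1)`, so the smallest value scores 0, the
#' largest scores 1, and tied values share a rank (the spreadsheet
#' PERCENTRANK convention evaluated at array members). For a descending
#' variable the same formula is applied to the negated values, so the largest
#' raw value scores 0. A single-value scope returns 1: a lone basin is
#' trivially top of its scope.
#'
#' @param values Numeric vector (optionally named by basin id).
#' @param direction `"ascending"` (larger raw value is more favorable) or
#'   `"descending"`.
#' @return Numeric vector of unit-interval ranks, same names as `values`.
#' @examples
#' percent_rank_scores(c(1, 2, 2, 3))            # 0, 1/3, 1/3, 1
#' percent_rank_scores(c(1, 2, 3), "descending") # 1, 0.5, 0
#' @export
percent_rank_scores <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (!length(values)) {
    abort("percent_rank_scores() needs at least one value.",
          class = "basinrank_domain_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("percent_rank_scores() requires finite values.",
          class = "basinrank_domain_error")
  }
  x <- if (direction == "descending") -values else values
  n <- length(x)
  if (n == 1L) {
    out <- 1
    names(out) <- names(values)
    return(out)
  }
  # rank(ties = "min") - 1 counts the values strictly below each element
  (rank(x, ties.method = "min") - 1) / (n - 1)
}

#' Weighted category score from variable ranks
#'
#' Sums weight-times-rank over the variables of one category and divides by
#' the normalizer: the number of variables (`by_variable_count`, the impact
#' convention, e.g. the four water-quality ranks weighted 1.5/0.5/1/1 and
#' divided by 4) or the total weight (`by_weight_sum`, the variability
#' convention, which puts every category on a `[0, 1]` scale). Missing ranks
#' are dropped and the normalizer shrinks accordingly, with a warning, so a
#' data gap is not scored as "least impacted".
#'
#' @param ranks Named numeric vector of unit-interval ranks, one per variable.
#' @param specs List of [variable_spec()]s for the category (names must match
#'   `ranks`).
#' @param normalization `"by_variable_count"` or `"by_weight_sum"`.
#' @return A single numeric score.
#' @export
category_score <- function(ranks, specs,
                           normalization = c("by_variable_count", "by_weight_sum")) {
  normalization <- match.arg(normalization)
  if (!length(specs)) {
    abort("category_score() called with an empty category.",
          class = "basinrank_config_error")
  }
  w <- vapply(specs, `[[`, numeric(1), "weight")
  nm <- vapply(specs, `[[`, character(1), "name")
  r <- ranks[nm]
  ok <- !is.na(r)
  if (!any(ok)) return(NA_real_)
  if (!all(ok)) {
    warn(sprintf("Dropping missing rank(s) for: %s; normalizer reduced.",
                 paste(nm[!ok], collapse = ", ")))
  }
  normalizer <- switch(normalization,
                       by_variable_count = sum(ok),
                       by_weight_sum = sum(w[ok]))
  sum(w[ok] * r[ok]) / normalizer
}

#' Overall score from category scores
#'
#' The weighted sum of category scores. The impact approach weights its three
#' categories (water quality, source, receptor) 1.0 each; the variability
#' approach weights water quality and factor 1.0 and receptor and accuracy
#' 0.5, for a maximum of 3.0 in both cases under unit-normalized categories.
#'
#' @param scores Named numeric vector of category scores.
#' @param category_weights Named numeric vector of weights; every name must
#'   be a category present in `scores`.
#' @return A single numeric overall score.
#' @export
overall_score <- function(scores, category_weights) {
  absent <- setdiff(names(category_weights), names(scores))
  if (length(absent)) {
    abort(sprintf("Weight given for absent category: %s.",
                  paste(absent, collapse = ", ")), class = "basinrank_config_error")
  }
  s <- scores[names(category_weights)]
  ok <- !is.na(s)
  sum(category_weights[ok] * s[ok])
}

# Rank every variable column of a variable table within scope groups.
# scope_index: integer/character vector assigning each basin to a ranking
# scope (a single group for roster-wide ranks, region_id for regional ranks).
.rank_variables <- function(var_table, config, scope_index) {
  ranks <- var_table[c("basin_id", "region_id")]
  groups <- split(seq_len(nrow(var_table)), scope_index)
  for (spec in config$variables) {
    vals <- var_table[[spec$name]]
    out <- rep(NA_real_, length(vals))
    for (idx in groups) {
      v <- vals[idx]
      ok <- !is.na(v)
      if (any(ok)) out[idx[ok]] <- percent_rank_scores(v[ok], spec$direction)
    }
    ranks[[spec$name]] <- out
  }
  ranks
}

# Category scores for every basin from a rank table.
.score_categories <- function(rank_table, config) {
  cats <- vapply(config$variables, `[[`, character(1), "category")
  out <- tibble::tibble(basin_id = rank_table$basin_id,
                        region_id = rank_table$region_id)
  for (ct in unique(cats)) {
    specs <- config$variables[cats == ct]
    nm <- vapply(specs, `[[`, character(1), "name")
    w <- vapply(specs, `[[`, numeric(1), "weight")
    mat <- as.matrix(rank_table[nm])
    ok <- !is.na(mat)
    if (!all(ok)) {
      warn(sprintf("Category '%s': %d missing rank value(s) dropped; normalizers reduced.",
                   ct, sum(!ok)))
    }
    wmat <- matrix(w, nrow(mat), ncol(mat), byrow = TRUE)
    num <- rowSums(wmat * mat, na.rm = TRUE)
    normalizer <- switch(config$category_normalization,
                         by_variable_count = rowSums(ok),
                         by_weight_sum = rowSums(wmat * ok))
    out[[ct]] <- ifelse(rowSums(ok) == 0L, NA_real_, num / normalizer)
  }
  out
}
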