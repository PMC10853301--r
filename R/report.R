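#' Select the top-n priority basins per region
#'
#' Reduces the candidate roster to the regional priority set: the `n` basins
#' with the smallest regional ordinals in each hydrologic region (fewer if a
#' region holds fewer basins). With 18 regions of at least two basins each
#' and `n = 2`, this yields the 36 priority basins.
#'
#' @param results Ranking result tibble from [run_impact()] or
#'   [run_variability()].
#' @param n Basins to keep per region (default 2).
#' @return A tibble (`region_id`, `basin_id`, `overall`, `region_ordinal`,
#'   `approach`) ordered by region then ordinal.
#' @export
select_top_n <- function(results, n = 2L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single integer >= 1.", class = "basinrank_domain_error")
  }
  approach <- attr(results, "approach") %||% NA_character_
  out <- tibble::as_tibble(results) |>
    dplyr::filter(.data$region_ordinal <= n) |>
    dplyr::transmute(region_id = .data$region_id, basin_id = .data$basin_id,
                     overall = .data$overall,
                     region_ordinal = .data$region_ordinal,
                     approach = approach) |>
    dplyr::arrange(.data$region_id, .data$region_ordinal, .data$basin_id)
  class(out) <- c("priority_set", class(out))
  out
}

#' Count regions whose top pick differs between two rankings
#'
#' Compares the ordinal-1 basin of every region between two ranking results
#' (typically the impact and variability approaches over the same roster).
#' The count is symmetric in its arguments.
#'
#' @param a,b Ranking result tibbles covering identical regions.
#' @return Integer count in `[0, number of regions]`.
#' @export
compare_top_picks <- function(a, b) {
  top <- function(r) {
    tibble::as_tibble(r) |>
      dplyr::filter(.data$region_ordinal == 1L) |>
      dplyr::select("region_id", "basin_id")
  }
  ta <- top(a); tb <- top(b)
  if (!setequal(ta$region_id, tb$region_id)) {
    abort("The two rankings cover different regions.",
          class = "basinrank_domain_error")
  }
  m <- dplyr::inner_join(ta, tb, by = "region_id", suffix = c("_a", "_b"))
  sum(m$basin_id_a != m$basin_id_b)
}

#' Per-region distribution summaries of category scores
#'
#' A tabular stand-in for violin plots: for every region and score category,
#' the minimum, 25th percentile, median, 75th percentile, and maximum of the
#' basin scores, plus the score of the region's top-ranked basin.
#'
#' @param results Ranking result tibble.
#' @return A tibble with one row per region and category.
#' @export
summarize_categories <- function(results) {
  df <- tibble::as_tibble(results)
  if (!nrow(df)) {
    abort("`results` must be non-empty.", class = "basinrank_domain_error")
  }
  cats <- intersect(.br_categories, names(df))
  long <- tidyr::pivot_longer(df[c("basin_id", "region_id", "region_ordinal", cats)],
                              cols = dplyr::all_of(cats),
                              names_to = "category", values_to = "score")
  long |>
    dplyr::group_by(.data$region_id, .data$category) |>
    dplyr::summarise(
      n_basins = dplyr::n(),
      min = min(.data$score),
      p25 = percentile(.data$score, 0.25),
      median = percentile(.data$score, 0.5),
      p75 = percentile(.data$score, 0.75),
      max = max(.data$score),
      top_basin_score = .data$score[.data$region_ordinal == 1L][1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region_id, .data$category)
}
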