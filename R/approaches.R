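#' Top-four water-quality eligibility penalty
#'
#' Within one hydrologic region, a basin is only eligible to win the
#' variability ranking if its water-quality category score is in the region's
#' top four; every other basin has 5 points subtracted from its water-quality
#' score, which effectively removes it from contention (the maximum
#' attainable overall score is 3). Basins tied with the fourth-highest score
#' all remain eligible, and regions with at most `top_k` basins are
#' unchanged.
#'
#' @param category_scores Tibble with at least `basin_id`, `region_id`, and
#'   `water_quality` columns (one region or many; the rule is applied within
#'   each region).
#' @param top_k Number of eligible basins per region (default 4).
#' @param penalty Points subtracted from the water-quality score (default 5).
#' @return The input with `water_quality` adjusted and a logical `penalized`
#'   column.
#' @examples
#' sc <- tibble::tibble(basin_id = letters[1:6], region_id = "r",
#'                      water_quality = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
#' apply_eligibility(sc)$water_quality
#' @export
apply_eligibility <- function(category_scores, top_k = 4L, penalty = 5) {
  if (top_k < 1) abort("`top_k` must be >= 1.", class = "basinrank_domain_error")
  df <- tibble::as_tibble(category_scores)
  df$penalized <- FALSE
  for (idx in split(seq_len(nrow(df)), df$region_id)) {
    wq <- df$water_quality[idx]
    if (length(idx) <= top_k || all(is.na(wq))) next
    threshold <- sort(wq, decreasing = TRUE)[top_k]
    hit <- !is.na(wq) & wq < threshold
    df$penalized[idx[hit]] <- TRUE
    df$water_quality[idx[hit]] <- wq[hit] - penalty
  }
  df
}

# Ordinals and unit-interval ranks from overall scores. Ordinal 1 is the
# highest-priority (highest-scoring) basin; exact ties break by basin_id.
.assign_ranks <- function(df) {
  ord_within <- function(overall, id) {
    o <- order(-overall, id)
    ord <- integer(length(o))
    ord[o] <- seq_along(o)
    ord
  }
  df$national_ordinal <- ord_within(df$overall, df$basin_id)
  df$national_unit_rank <- percent_rank_scores(df$overall)
  df$region_ordinal <- NA_integer_
  df$region_unit_rank <- NA_real_
  for (idx in split(seq_len(nrow(df)), df$region_id)) {
    df$region_ordinal[idx] <- ord_within(df$overall[idx], df$basin_id[idx])
    df$region_unit_rank[idx] <- percent_rank_scores(df$overall[idx])
  }
  df
}

.run_approach <- function(basins, subbasins, config, scope) {
  v <- validate_tables(basins, subbasins)
  var_table <- build_variable_table(v$basins, v$subbasins, config)
  scope_index <- if (scope == "region") var_table$region_id else
    rep_len("roster", nrow(var_table))
  rank_table <- .rank_variables(var_table, config, scope_index)
  scores <- .score_categories(rank_table, config)
  elig <- config$eligibility
  if (isTRUE(elig$enabled) && identical(scope, elig$scope)) {
    scores <- apply_eligibility(scores, top_k = elig$top_k, penalty = elig$penalty)
    if (any(scores$penalized)) {
      inform(sprintf("Eligibility penalty applied to %d basin(s) outside their region's top-%d water-quality scores.",
                     sum(scores$penalized), elig$top_k))
    }
  } else {
    scores$penalized <- FALSE
  }
  cats <- intersect(.br_categories, names(scores))
  smat <- as.matrix(scores[cats])
  scores$overall <- apply(smat, 1L, function(s) {
    overall_score(stats::setNames(s, cats), config$category_weights)
  })
  res <- .assign_ranks(scores)
  cols <- c("basin_id", "region_id", cats, "penalized", "overall",
            "region_ordinal", "national_ordinal",
            "region_unit_rank", "national_unit_rank")
  res <- res[cols]
  attr(res, "approach") <- config$approach
  attr(res, "scope") <- scope
  class(res) <- c("basinrank_result", class(res))
  res
}

#' Rank basins with the impact approach
#'
#' Scores every candidate basin on 14 variables describing nutrient water
#' quality (stream N and P medians over HUC08 subbasins, shallow and
#' public-supply-depth groundwater nitrate), anthropogenic sources (fertilizer
#' plus manure, wastewater, septic yields), and receptors (population served,
#' percent waterbodies, biotic condition, delivered N and P yields). Variable
#' percent ranks are always computed across the full roster — regional
#' rankings reuse the roster-wide ranks so small within-region differences do
#' not dominate — and the overall score is the unweighted sum of the three
#' category scores.
#'
#' @param basins,subbasins Input tables (see [load_tables()]).
#' @param config A [ranking_config()]; defaults to the shipped impact
#'   configuration.
#' @return A tibble with one row per basin: category scores, `overall`,
#'   `region_ordinal` and `national_ordinal` (1 = highest priority), and
#'   unit-interval ranks.
#' @examples
#' roster <- generate_roster(synthetic_config(seed = 1))
#' res <- run_impact(roster$basins, roster$subbasins)
#' res[res$national_ordinal <= 3, c("basin_id", "overall")]
#' @export
run_impact <- function(basins, subbasins, config = default_config("impact")) {
  if (!identical(config$approach, "impact")) {
    abort("run_impact() needs a config with approach = 'impact'.",
          class = "basinrank_config_error")
  }
  .run_approach(basins, subbasins, config, scope = "national")
}

#' Rank basins with the variability approach
#'
#' Scores every candidate basin on 20 variables that favor good study sites:
#' wide interquartile ranges of log-transformed stream N and P concentrations
#' across HUC08 subbasins, low minimum concentrations (ranked descending,
#' because biological response is strongest at low concentrations), wide
#' ranges in the factors driving concentrations (sources, tile drainage,
#' runoff, groundwater nitrate), large watershed-model residual magnitudes
#' (poorly predicted basins have the most to teach), and receptor exposure.
#' With `scope = "region"` variable ranks are computed within each hydrologic
#' region and the top-four water-quality eligibility penalty is applied;
#' with `scope = "national"` ranks span the roster and no penalty is applied
#' by default.
#'
#' @inheritParams run_impact
#' @param scope `"region"` or `"national"` ranking scope.
#' @return A tibble as in [run_impact()], with an `accuracy` category column
#'   and a `penalized` flag.
#' @export
run_variability <- function(basins, subbasins,
                            config = default_config("variability"),
                            scope = c("region", "national")) {
  scope <- match.arg(scope)
  if (!identical(config$approach, "variability")) {
    abort("run_variability() needs a config with approach = 'variability'.",
          class = "basinrank_config_error")
  }
  .run_approach(basins, subbasins, config, scope = scope)
}
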