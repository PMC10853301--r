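# Canonical CSV schemas for the two input tables
.br_basin_cols <- c("basin_id", "region_id", "area_km2", "pop_served_per_km2",
                    "pct_waterbodies", "biotic_index",
                    "delivered_N_yield", "delivered_P_yield")
.br_subbasin_cols <- c("huc08_id", "basin_id", "stream_N_vwm", "stream_P_vwm",
                       "fertmanure_N", "fertmanure_P", "wwtp_N", "wwtp_P",
                       "septic_N", "tile_fraction", "runoff",
                       "gw_shallow_no3", "gw_ps_no3", "resid_N", "resid_P")

# Columns that must be non-negative where present (residuals are signed)
.br_nonneg_sub <- c("stream_N_vwm", "stream_P_vwm", "fertmanure_N", "fertmanure_P",
                    "wwtp_N", "wwtp_P", "septic_N", "runoff",
                    "gw_shallow_no3", "gw_ps_no3")

.apply_aliases <- function(df, aliases) {
  if (is.null(aliases)) return(df)
  hits <- intersect(names(aliases), names(df))
  names(df)[match(hits, names(df))] <- unname(aliases[hits])
  df
}

.check_bounds <- function(df, table, col, lo, hi, id_col) {
  bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
  if (length(bad)) {
    abort(sprintf("%s: '%s' out of [%g, %g] for %s %s (row %d).",
                  table, col, lo, hi, id_col, df[[id_col]][bad[1]], bad[1]),
          class = "basinrank_validation_error")
  }
}

#' Validate a pair of basin / subbasin tables
#'
#' Checks the documented CSV schemas: required columns, unique identifiers,
#' positive areas, unit-interval tile fractions and biotic indices,
#' percentages in `[0, 100]`, non-negative concentrations and yields, and
#' that every subbasin references an existing basin.
#'
#' @param basins Basin table (one row per candidate basin).
#' @param subbasins Subbasin table (one row per HUC08).
#' @return Invisibly, `list(basins, subbasins)` as tibbles with identifier
#'   columns coerced to character.
#' @export
validate_tables <- function(basins, subbasins) {
  basins <- tibble::as_tibble(basins)
  subbasins <- tibble::as_tibble(subbasins)
  miss_b <- setdiff(.br_basin_cols, names(basins))
  if (length(miss_b)) {
    abort(sprintf("basins table is missing required column(s): %s.",
                  paste(miss_b, collapse = ", ")), class = "basinrank_schema_error")
  }
  miss_s <- setdiff(.br_subbasin_cols, names(subbasins))
  if (length(miss_s)) {
    abort(sprintf("subbasins table is missing required column(s): %s.",
                  paste(miss_s, collapse = ", ")), class = "basinrank_schema_error")
  }
  basins$basin_id <- as.character(basins$basin_id)
  basins$region_id <- as.character(basins$region_id)
  subbasins$huc08_id <- as.character(subbasins$huc08_id)
  subbasins$basin_id <- as.character(subbasins$basin_id)

  if (anyDuplicated(basins$basin_id)) {
    abort("basins: duplicate basin_id.", class = "basinrank_validation_error")
  }
  if (anyDuplicated(subbasins$huc08_id)) {
    abort("subbasins: duplicate huc08_id.", class = "basinrank_validation_error")
  }
  bad_area <- which(!is.finite(basins$area_km2) | basins$area_km2 <= 0)
  if (length(bad_area)) {
    abort(sprintf("basins: 'area_km2' must be > 0 for basin_id %s (row %d).",
                  basins$basin_id[bad_area[1]], bad_area[1]),
          class = "basinrank_validation_error")
  }
  .check_bounds(basins, "basins", "biotic_index", 0, 1, "basin_id")
  .check_bounds(basins, "basins", "pct_waterbodies", 0, 100, "basin_id")
  for (col in c("pop_served_per_km2", "delivered_N_yield", "delivered_P_yield")) {
    .check_bounds(basins, "basins", col, 0, Inf, "basin_id")
  }
  .check_bounds(subbasins, "subbasins", "tile_fraction", 0, 1, "huc08_id")
  for (col in .br_nonneg_sub) {
    .check_bounds(subbasins, "subbasins", col, 0, Inf, "huc08_id")
  }
  orphans <- setdiff(subbasins$basin_id, basins$basin_id)
  if (length(orphans)) {
    abort(sprintf("subbasins reference unknown basin_id(s): %s.",
                  paste(utils::head(orphans, 5), collapse = ", ")),
          class = "basinrank_referential_error")
  }
  no_sub <- setdiff(basins$basin_id, subbasins$basin_id)
  if (length(no_sub)) {
    abort(sprintf("basin(s) without any subbasin: %s.",
                  paste(utils::head(no_sub, 5), collapse = ", ")),
          class = "basinrank_referential_error")
  }
  invisible(list(basins = basins, subbasins = subbasins))
}

#' Read and validate the basin and subbasin tables
#'
#' @param basin_path,subbasin_path Paths to CSV files following the
#'   documented schemas (`basins.csv`, `subbasins.csv`).
#' @param aliases Optional named character vector mapping a file's column
#'   names to the canonical ones (`c(my_col = "canonical_col")`), so exports
#'   with different headers can be ingested without editing the file.
#' @return `list(basins, subbasins)` of validated tibbles.
#' @examples
#' roster <- generate_roster(synthetic_config(seed = 1))
#' dir <- tempfile(); dir.create(dir)
#' write_tables(roster, dir)
#' reread <- load_tables(file.path(dir, "basins.csv"), file.path(dir, "subbasins.csv"))
#' nrow(reread$basins)
#' @export
load_tables <- function(basin_path, subbasin_path, aliases = NULL) {
  for (p in c(basin_path, subbasin_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p), class = "basinrank_io_error")
  }
  basins <- readr::read_csv(basin_path, show_col_types = FALSE, progress = FALSE)
  subbasins <- readr::read_csv(subbasin_path, show_col_types = FALSE, progress = FALSE)
  basins <- .apply_aliases(basins, aliases)
  subbasins <- .apply_aliases(subbasins, aliases)
  validate_tables(basins, subbasins)
}

#' Write a synthetic or imported roster to CSV
#'
#' @param tables `list(basins, subbasins)`.
#' @param dir Output directory (created if absent); writes `basins.csv` and
#'   `subbasins.csv`.
#' @return Invisibly, the two file paths.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("basins.csv", "subbasins.csv"))
  readr::write_csv(tables$basins, paths[1], progress = FALSE)
  readr::write_csv(tables$subbasins, paths[2], progress = FALSE)
  invisible(paths)
}

#' Write ranking results to CSV
#'
#' One row per basin with category scores, the overall score, regional and
#' national ordinal ranks, and unit-interval ranks, ordered by national
#' ordinal then basin id so repeated runs produce byte-identical files.
#'
#' @param results Ranking result tibble from [run_impact()] or
#'   [run_variability()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_rankings <- function(results, path) {
  if (!is.data.frame(results) || !nrow(results)) {
    abort("`results` must be a non-empty ranking result table.",
          class = "basinrank_validation_error")
  }
  if (anyDuplicated(results$basin_id)) {
    abort("Duplicate basin_id in ranking results.",
          class = "basinrank_validation_error")
  }
  out <- dplyr::arrange(tibble::as_tibble(results), .data$national_ordinal, .data$basin_id)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
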