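test_that("a basin planted at every impact maximum is ranked first nationally", {
  roster <- generate_roster(synthetic_config(n_regions = 6, seed = 21))
  planted <- plant_extreme(roster, "R03", "impact_dominant")
  target <- attr(planted, "plants")[[1]]$basin_id
  res <- run_impact(planted$basins, planted$subbasins)
  expect_equal(res$national_ordinal[res$basin_id == target], 1L)
  expect_equal(res$region_ordinal[res$basin_id == target], 1L)
  # all 14 roster-wide variable ranks are 1 -> categories at their maxima
  row <- res[res$basin_id == target, ]
  expect_equal(row$water_quality, 1)
  expect_equal(row$source, 1)
  expect_equal(row$receptor, 0.8)  # five receptor variables, total weight 4
  expect_equal(row$overall, 2.8)
})

test_that("identical basins tie everywhere and a singleton roster scores 2.8", {
  tabs <- tiny_tables()
  # make all three basins identical on every variable
  tabs$basins[2:3, -(1:2)] <- tabs$basins[rep(1, 2), -(1:2)]
  tabs$subbasins[4:9, -(1:2)] <- tabs$subbasins[rep(1:3, 2), -(1:2)]
  res <- run_impact(tabs$basins, tabs$subbasins)
  expect_equal(length(unique(res$overall)), 1L)

  solo <- tiny_tables()
  solo$basins <- solo$basins[1, ]
  solo$subbasins <- solo$subbasins[1:3, ]
  res1 <- run_impact(solo$basins, solo$subbasins)
  expect_equal(res1$overall, 1 + 1 + 0.8)
  expect_equal(res1$region_ordinal, 1L)
})

test_that("eligibility penalizes basins outside the top four water-quality scores", {
  sc <- tibble::tibble(basin_id = letters[1:6], region_id = "r",
                       water_quality = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  out <- apply_eligibility(sc)
  expect_equal(out$water_quality, c(0.9, 0.8, 0.7, 0.6, -4.5, -4.6))
  expect_equal(out$penalized, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))

  # ties at the fourth-highest score keep everyone eligible
  tie <- tibble::tibble(basin_id = letters[1:5], region_id = "r",
                        water_quality = c(0.9, 0.8, 0.7, 0.6, 0.6))
  expect_false(any(apply_eligibility(tie)$penalized))

  # small regions are untouched
  small <- tibble::tibble(basin_id = letters[1:3], region_id = "r",
                          water_quality = c(0.9, 0.5, 0.1))
  expect_equal(apply_eligibility(small)$water_quality, small$water_quality)
})

test_that("a penalized basin scores below every unpenalized basin in its region", {
  roster <- generate_roster(synthetic_config(seed = 33))
  res <- suppressMessages(run_variability(roster$basins, roster$subbasins))
  for (rid in unique(res$region_id)) {
    rr <- res[res$region_id == rid, ]
    if (any(rr$penalized) && any(!rr$penalized)) {
      expect_lt(max(rr$overall[rr$penalized]), min(rr$overall[!rr$penalized]))
    }
  }
  # hence every regional winner sits in its region's water-quality top four
  expect_false(any(res$penalized[res$region_ordinal == 1L]))
})

test_that("a variability-dominant plant wins its region", {
  roster <- generate_roster(synthetic_config(n_regions = 5, seed = 44))
  planted <- plant_extreme(roster, "R02", "variability_dominant")
  target <- attr(planted, "plants")[[1]]$basin_id
  res <- suppressMessages(run_variability(planted$basins, planted$subbasins))
  expect_equal(res$region_ordinal[res$basin_id == target], 1L)
  expect_false(res$penalized[res$basin_id == target])
})

test_that("both pipelines are deterministic across repeated runs", {
  roster <- generate_roster(synthetic_config(n_regions = 4, seed = 3))
  a <- run_impact(roster$basins, roster$subbasins)
  b <- run_impact(roster$basins, roster$subbasins)
  expect_identical(a, b)
  va <- suppressMessages(run_variability(roster$basins, roster$subbasins))
  vb <- suppressMessages(run_variability(roster$basins, roster$subbasins))
  expect_identical(va, vb)
})

test_that("impact variable ranks are computed across the full roster", {
  # regional orderings can change when another region's basins are removed,
  # because variable percent ranks always span the whole roster
  roster <- generate_roster(synthetic_config(n_regions = 3, seed = 9))
  full <- run_impact(roster$basins, roster$subbasins)
  keep_b <- roster$basins[roster$basins$region_id != "R03", ]
  keep_s <- roster$subbasins[roster$subbasins$basin_id %in% keep_b$basin_id, ]
  part <- run_impact(keep_b, keep_s)
  joined <- dplyr::inner_join(full, part, by = "basin_id",
                              suffix = c("_full", "_part"))
  expect_false(isTRUE(all.equal(joined$overall_full, joined$overall_part)))
})

test_that("with equal weights and no penalty, scores reduce to means of ranks", {
  roster <- generate_roster(synthetic_config(n_regions = 3, seed = 55))
  cfg <- default_config("impact")
  flat_vars <- lapply(cfg$variables, function(v) { v$weight <- 1; v })
  flat <- ranking_config("impact", flat_vars,
                         category_weights = c(water_quality = 1, source = 1, receptor = 1),
                         category_normalization = "by_variable_count")
  res <- run_impact(roster$basins, roster$subbasins, flat)

  # independent path: brute-force aggregation, pairwise percent ranks,
  # per-category means, summed
  vt <- build_variable_table(roster$basins, roster$subbasins, flat)
  cats <- vapply(flat$variables, `[[`, character(1), "category")
  expected <- rep(0, nrow(vt))
  for (ct in unique(cats)) {
    nm <- names(flat$variables)[cats == ct]
    rank_mat <- sapply(nm, function(v) brute_percent_rank(vt[[v]]))
    expected <- expected + rowMeans(rank_mat)
  }
  expect_equal(res$overall[match(vt$basin_id, res$basin_id)], expected,
               tolerance = 1e-12)
})
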