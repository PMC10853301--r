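test_that("percent rank handles distinct values, ties, and descending direction", {
  expect_equal(percent_rank_scores(1:5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(percent_rank_scores(c(1, 2, 2, 3)), c(0, 1/3, 1/3, 1))
  expect_equal(percent_rank_scores(c(1, 2, 3), "descending"), c(1, 0.5, 0))
  expect_equal(percent_rank_scores(42), 1)  # a lone basin is trivially top
  expect_error(percent_rank_scores(c(1, NA)), class = "basinrank_domain_error")
  expect_error(percent_rank_scores(c(1, Inf)), class = "basinrank_domain_error")
})

test_that("percent rank equals the pairwise oracle on every small multiset", {
  for (n in 1:8) {
    sets <- all_multisets(n, 0:3)
    for (i in seq_len(nrow(sets))) {
      v <- as.numeric(sets[i, ])
      expect_identical(percent_rank_scores(v), brute_percent_rank(v))
    }
  }
})

test_that("descending percent rank equals ascending rank of negated values", {
  set.seed(31)
  for (i in 1:25) {
    v <- sample(0:5, sample(2:10, 1), replace = TRUE)
    expect_equal(percent_rank_scores(v, "descending"), percent_rank_scores(-v))
  }
})

test_that("category scores evaluate the published water-quality equation", {
  specs <- list(
    variable_spec("shallow", "water_quality", "a", aggregation = "median", weight = 1.5),
    variable_spec("ps", "water_quality", "b", aggregation = "median", weight = 0.5),
    variable_spec("swN", "water_quality", "c", aggregation = "median", weight = 1.0),
    variable_spec("swP", "water_quality", "d", aggregation = "median", weight = 1.0))
  all_one <- c(shallow = 1, ps = 1, swN = 1, swP = 1)
  expect_equal(category_score(all_one, specs, "by_variable_count"), 1.0)
  expect_equal(category_score(c(shallow = 1, ps = 0, swN = 0, swP = 0),
                              specs, "by_variable_count"), 0.375)
  expect_equal(category_score(c(shallow = 0, ps = 0, swN = 0, swP = 0),
                              specs, "by_variable_count"), 0)
  # weight-sum normalization puts the top score at exactly 1 as well
  expect_equal(category_score(all_one, specs, "by_weight_sum"), 1.0)
  expect_equal(category_score(c(shallow = 1, ps = 0, swN = 0, swP = 0),
                              specs, "by_weight_sum"), 1.5 / 4)
  expect_error(category_score(all_one, list(), "by_weight_sum"),
               class = "basinrank_config_error")
})

test_that("missing ranks are dropped with a shrunken normalizer", {
  specs <- list(
    variable_spec("a", "factor", "a", aggregation = "iqr_range", weight = 1),
    variable_spec("b", "factor", "b", aggregation = "iqr_range", weight = 0.5))
  expect_warning(
    s <- category_score(c(a = 0.8, b = NA), specs, "by_weight_sum"),
    "normalizer reduced")
  expect_equal(s, 0.8)
})

test_that("overall scores evaluate the published combination equations", {
  expect_equal(overall_score(c(water_quality = 1, source = 1, receptor = 1),
                             c(water_quality = 1, source = 1, receptor = 1)), 3)
  expect_equal(overall_score(
    c(water_quality = 1, factor = 1, receptor = 1, accuracy = 1),
    c(water_quality = 1, factor = 1, receptor = 0.5, accuracy = 0.5)), 3)
  expect_equal(overall_score(c(water_quality = 0, source = 0, receptor = 0),
                             c(water_quality = 1, source = 1, receptor = 1)), 0)
  expect_error(overall_score(c(water_quality = 1, source = 1),
                             c(water_quality = 1, receptor = 1)),
               class = "basinrank_config_error")
})

test_that("scores are invariant to the order of input rows", {
  tabs <- tiny_tables()
  base <- run_impact(tabs$basins, tabs$subbasins)
  perm_b <- tabs$basins[c(3, 1, 2), ]
  perm_s <- tabs$subbasins[sample(9), ]
  perm <- run_impact(perm_b, perm_s)
  expect_equal(dplyr::arrange(perm, basin_id), dplyr::arrange(base, basin_id),
               ignore_attr = TRUE)
})

test_that("raising one ascending raw value never lowers that basin's scores", {
  roster <- generate_roster(synthetic_config(n_regions = 4, seed = 5))
  before_i <- run_impact(roster$basins, roster$subbasins)
  before_v <- suppressMessages(
    run_variability(roster$basins, roster$subbasins, scope = "national"))
  target <- roster$basins$basin_id[7]

  check_not_lower <- function(before, after, cols) {
    b <- before[before$basin_id == target, ]
    a <- after[after$basin_id == target, ]
    for (col in c(cols, "overall")) expect_gte(a[[col]], b[[col]])
    expect_lte(a$national_ordinal, b$national_ordinal)
  }

  # basin-level receptor variable: ascending in both approaches
  r2 <- roster
  r2$basins$pop_served_per_km2[r2$basins$basin_id == target] <-
    max(r2$basins$pop_served_per_km2) * 2
  check_not_lower(before_i, run_impact(r2$basins, r2$subbasins),
                  c("water_quality", "source", "receptor"))
  after_v <- suppressMessages(
    run_variability(r2$basins, r2$subbasins, scope = "national"))
  check_not_lower(before_v, after_v, "receptor")

  # subbasin stream concentration: ascending in the impact approach (raises
  # the basin median weakly); not ascending for variability, where the
  # minimum concentration ranks descending
  r3 <- roster
  i <- which(r3$subbasins$basin_id == target)
  r3$subbasins$stream_N_vwm[i] <- r3$subbasins$stream_N_vwm[i] * 3
  check_not_lower(before_i, run_impact(r3$basins, r3$subbasins),
                  c("water_quality", "source", "receptor"))
})
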