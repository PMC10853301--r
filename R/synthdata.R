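# Subbasin columns that carry positive, skewed quantities whose basin-level
# spread/level is scored by one approach or the other.
.br_spread_cols <- c("stream_N_vwm", "stream_P_vwm", "fertmanure_N", "fertmanure_P",
                     "wwtp_N", "wwtp_P", "septic_N", "tile_fraction", "runoff",
                     "gw_shallow_no3", "gw_ps_no3")
.br_receptor_cols <- c("pop_served_per_km2", "pct_waterbodies", "biotic_index",
                       "delivered_N_yield", "delivered_P_yield")

.default_sim_params <- function() {
  list(
    # log-normal locations (meanlog, natural log) and scales for source
    # yields (kg/km2/yr) and concentrations (mg/L); region-to-region spread
    # of the locations first, then subbasin-level scale
    fm_N_meanlog = log(1500), fm_N_region_sd = 0.6, fm_N_sub_sd = 0.5,
    fm_P_ratio_meanlog = log(0.15), fm_P_ratio_sd = 0.2,
    wwtp_N_meanlog = log(40), wwtp_N_region_sd = 0.8, wwtp_N_sub_sd = 0.9,
    wwtp_P_ratio_meanlog = log(0.2), wwtp_P_ratio_sd = 0.3,
    septic_N_meanlog = log(25), septic_N_region_sd = 0.6, septic_N_sub_sd = 0.6,
    stream_N_log10_mu = log10(1.2), stream_N_region_sd = 0.25, stream_N_sub_sd = 0.35,
    stream_P_log10_mu = log10(0.08), stream_P_region_sd = 0.25, stream_P_sub_sd = 0.35,
    gw_shallow_log10_mu = log10(2.5), gw_region_sd = 0.25, gw_sub_sd = 0.3,
    gw_ps_ratio_meanlog = log(0.4), gw_ps_ratio_sd = 0.4,
    basin_effect_sd = 0.3,        # shared log-space basin effect within a region
    tile_shape1 = c(0.6, 2.5),    # per-region Beta shape ranges for tile fraction
    tile_shape2 = c(2.5, 9),
    runoff_shape = 2, runoff_mean_range = c(0.05, 0.9),  # Gamma, m/yr
    biotic_shape1 = 2, biotic_shape2 = 2,
    resid_sd_range = c(10, 40),   # per-region sd of signed log-space percent error
    area_meanlog = log(15000), area_sd = 0.3,
    pop_meanlog = log(30), pop_sd = 1,
    waterbody_shape1 = 1.2, waterbody_shape2 = 18,
    delivered_N_meanlog = log(300), delivered_P_meanlog = log(30), delivered_sd = 0.7
  )
}

#' Configure the synthetic roster generator
#'
#' Describes a roster of candidate basins grouped into hydrologic regions,
#' each basin holding several HUC08 subbasins, with the statistical structure
#' the ranking pipelines assume: positively skewed (log-normal) source yields
#' and stream/groundwater concentrations with region- and basin-level
#' effects, Beta-distributed tile-drain fractions and biotic indices,
#' Gamma-distributed runoff, signed Normal model residuals in log space, and
#' a tunable monotone coupling between local source yields and stream
#' concentrations.
#'
#' @param n_regions Number of hydrologic regions (default 18).
#' @param basins_per_region Integer vector (recycled) of basins per region;
#'   the default places 163 basins across 18 regions.
#' @param subbasins_per_basin Length-2 integer range; each basin draws its
#'   subbasin count uniformly from it (default 4 to 12).
#' @param coupling Source-to-concentration coupling coefficient in `[0, 1]`:
#'   0 makes stream concentrations independent of source yields, 1 makes
#'   them a deterministic monotone function of them.
#' @param planted_extremes Optional list of `list(region =, mode =)` entries,
#'   `mode` one of `"impact_dominant"`, `"variability_dominant"`; see
#'   [plant_extreme()].
#' @param seed Integer seed; identical seed and config reproduce the roster
#'   exactly. Per-region substreams are derived deterministically from it.
#' @param params Named list overriding entries of the default distribution
#'   parameters (see source of `basinrank:::.default_sim_params`).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 18L,
                             basins_per_region = NULL,
                             subbasins_per_basin = c(4L, 12L),
                             coupling = 0.6,
                             planted_extremes = list(),
                             seed = 1L,
                             params = list()) {
  if (n_regions < 1) abort("`n_regions` must be >= 1.", class = "basinrank_config_error")
  if (is.null(basins_per_region)) {
    basins_per_region <- rep(9L, n_regions)
    extra <- 163L - sum(basins_per_region)
    if (n_regions == 18L && extra > 0) {
      basins_per_region[seq_len(extra)] <- basins_per_region[seq_len(extra)] + 1L
    }
  }
  basins_per_region <- rep_len(as.integer(basins_per_region), n_regions)
  if (any(basins_per_region < 1)) {
    abort("Every region needs at least one basin.", class = "basinrank_config_error")
  }
  if (length(subbasins_per_basin) != 2L || any(subbasins_per_basin < 1) ||
      subbasins_per_basin[1] > subbasins_per_basin[2]) {
    abort("`subbasins_per_basin` must be an increasing length-2 range of positive integers.",
          class = "basinrank_config_error")
  }
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1) {
    abort("`coupling` must lie in [0, 1].", class = "basinrank_config_error")
  }
  if (length(planted_extremes)) {
    keys <- vapply(planted_extremes, function(p) {
      if (is.null(p$region) || is.null(p$mode) ||
          !p$mode %in% c("impact_dominant", "variability_dominant")) {
        abort("Each planted extreme needs a region and a mode of 'impact_dominant' or 'variability_dominant'.",
              class = "basinrank_config_error")
      }
      paste(p$region, p$mode)
    }, character(1))
    if (anyDuplicated(keys)) {
      abort("Duplicate planted extreme (same region and mode twice).",
            class = "basinrank_config_error")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "basinrank_config_error")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         basins_per_region = basins_per_region,
         subbasins_per_basin = as.integer(subbasins_per_basin),
         coupling = coupling,
         planted_extremes = planted_extremes,
         seed = as.integer(seed),
         params = utils::modifyList(.default_sim_params(), params)),
    class = "synthetic_config"
  )
}

# Deterministic per-region substream seed below 2^31.
.region_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + r * 7919) %% 2147483647)
}

.gen_region <- function(cfg, r) {
  p <- cfg$params
  set.seed(.region_seed(cfg$seed, r))
  n_b <- cfg$basins_per_region[r]
  region_id <- sprintf("R%02d", r)

  # region-level locations
  mu_fmN <- p$fm_N_meanlog + rnorm(1, 0, p$fm_N_region_sd)
  mu_wwN <- p$wwtp_N_meanlog + rnorm(1, 0, p$wwtp_N_region_sd)
  mu_sep <- p$septic_N_meanlog + rnorm(1, 0, p$septic_N_region_sd)
  mu_cN <- p$stream_N_log10_mu + rnorm(1, 0, p$stream_N_region_sd)
  mu_cP <- p$stream_P_log10_mu + rnorm(1, 0, p$stream_P_region_sd)
  mu_gw <- p$gw_shallow_log10_mu + rnorm(1, 0, p$gw_region_sd)
  tile_a <- runif(1, p$tile_shape1[1], p$tile_shape1[2])
  tile_b <- runif(1, p$tile_shape2[1], p$tile_shape2[2])
  runoff_mean <- runif(1, p$runoff_mean_range[1], p$runoff_mean_range[2])
  resid_sd <- runif(1, p$resid_sd_range[1], p$resid_sd_range[2])

  basin_id <- sprintf("%s_B%02d", region_id, seq_len(n_b))
  n_sub <- sample(cfg$subbasins_per_basin[1]:cfg$subbasins_per_basin[2],
                  n_b, replace = TRUE)
  b_eff <- rnorm(n_b, 0, p$basin_effect_sd)

  basins <- tibble::tibble(
    basin_id = basin_id,
    region_id = region_id,
    area_km2 = rlnorm(n_b, p$area_meanlog, p$area_sd),
    pop_served_per_km2 = rlnorm(n_b, p$pop_meanlog, p$pop_sd),
    pct_waterbodies = 100 * rbeta(n_b, p$waterbody_shape1, p$waterbody_shape2),
    biotic_index = rbeta(n_b, p$biotic_shape1, p$biotic_shape2),
    delivered_N_yield = rlnorm(n_b, p$delivered_N_meanlog, p$delivered_sd),
    delivered_P_yield = rlnorm(n_b, p$delivered_P_meanlog, p$delivered_sd)
  )

  m <- sum(n_sub)
  bi <- rep(seq_len(n_b), n_sub)             # basin index per subbasin row
  eff <- b_eff[bi]
  sd_tot <- sqrt(p$basin_effect_sd^2 + p$fm_N_sub_sd^2)

  log_fmN <- mu_fmN + eff + rnorm(m, 0, p$fm_N_sub_sd)
  fm_N <- exp(log_fmN)
  fm_P <- fm_N * exp(rnorm(m, p$fm_P_ratio_meanlog, p$fm_P_ratio_sd))
  wwtp_N <- exp(mu_wwN + eff + rnorm(m, 0, p$wwtp_N_sub_sd))
  wwtp_P <- wwtp_N * exp(rnorm(m, p$wwtp_P_ratio_meanlog, p$wwtp_P_ratio_sd))
  septic_N <- exp(mu_sep + eff + rnorm(m, 0, p$septic_N_sub_sd))

  # stream and groundwater concentrations: a coupling-weighted blend of the
  # standardized local source signal and independent noise, mapped through a
  # log-normal, so source-rich subbasins carry high concentrations in
  # expectation when coupling is high
  z_src <- (log_fmN - mu_fmN) / sd_tot
  mix <- function(noise) cfg$coupling * z_src + sqrt(1 - cfg$coupling^2) * noise
  stream_N <- 10^(mu_cN + p$stream_N_sub_sd * mix(rnorm(m)))
  stream_P <- 10^(mu_cP + p$stream_P_sub_sd * mix(rnorm(m)))
  gw_shallow <- 10^(mu_gw + p$gw_sub_sd * mix(rnorm(m)))
  gw_ps <- gw_shallow * exp(rnorm(m, p$gw_ps_ratio_meanlog, p$gw_ps_ratio_sd))

  subbasins <- tibble::tibble(
    huc08_id = sprintf("%s_S%02d", basin_id[bi],
                       unlist(lapply(n_sub, seq_len), use.names = FALSE)),
    basin_id = basin_id[bi],
    stream_N_vwm = stream_N,
    stream_P_vwm = stream_P,
    fertmanure_N = fm_N,
    fertmanure_P = fm_P,
    wwtp_N = wwtp_N,
    wwtp_P = wwtp_P,
    septic_N = septic_N,
    tile_fraction = rbeta(m, tile_a, tile_b),
    runoff = rgamma(m, shape = p$runoff_shape,
                    rate = p$runoff_shape / runoff_mean),
    gw_shallow_no3 = gw_shallow,
    gw_ps_no3 = gw_ps,
    resid_N = rnorm(m, 0, resid_sd),
    resid_P = rnorm(m, 0, resid_sd)
  )
  list(basins = basins, subbasins = subbasins)
}

#' Generate a seeded synthetic roster
#'
#' Builds the basin and subbasin tables described by a [synthetic_config()].
#' Identical configurations (including the seed) reproduce the roster
#' bit-for-bit; per-region random substreams are derived deterministically
#' from the single seed. Stream concentrations are generated as a monotone
#' function of local source yields plus independent noise, with the blend set
#' by the coupling coefficient, so the source-to-water-quality association
#' seen in real rosters is reproducible in expectation.
#'
#' @param config A [synthetic_config()].
#' @return `list(basins, subbasins)` of validated tibbles.
#' @examples
#' roster <- generate_roster(synthetic_config(seed = 42))
#' nrow(roster$basins)
#' @export
generate_roster <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().",
          class = "basinrank_config_error")
  }
  parts <- lapply(seq_len(config$n_regions), function(r) .gen_region(config, r))
  tables <- list(
    basins = dplyr::bind_rows(lapply(parts, `[[`, "basins")),
    subbasins = dplyr::bind_rows(lapply(parts, `[[`, "subbasins"))
  )
  for (pe in config$planted_extremes) {
    region <- if (is.numeric(pe$region)) sprintf("R%02d", pe$region) else pe$region
    tables <- plant_extreme(tables, region, pe$mode)
  }
  validate_tables(tables$basins, tables$subbasins)
  tables
}

#' Plant an extreme basin as a ranking oracle
#'
#' Overwrites one basin of the chosen region so that its rank under one
#' approach is known by construction. `impact_dominant` sets every
#' impact-approach variable (all subbasin concentrations and source yields,
#' all basin receptor values) strictly beyond the roster maximum (1% past
#' it, capped at hard supports such as 100% waterbodies), so the basin must
#' come out first nationally under [run_impact()]. `variability_dominant`
#' gives the region's largest basin (most subbasins) the widest possible
#' subbasin spread — half its subbasins just below the roster minimum and
#' half just above the roster maximum of every spread variable — hence also
#' the lowest minimum stream concentrations, plus the largest model-residual
#' magnitudes and receptor values, so it must come out first in its region
#' under [run_variability()]. The margin beyond the extremes keeps the
#' plant's percent ranks at exactly 1 under the strictly-less tie
#' convention, where a value merely tied with the maximum would rank below 1.
#'
#' The basin's original rows are kept in an attribute so [unplant()] can
#' restore the unmodified tables.
#'
#' @param tables `list(basins, subbasins)`.
#' @param region Region identifier to plant in.
#' @param mode `"impact_dominant"` or `"variability_dominant"`.
#' @return The modified tables, with a `plants` attribute recording the
#'   planted basin ids and their original rows.
#' @export
plant_extreme <- function(tables, region, mode) {
  if (!mode %in% c("impact_dominant", "variability_dominant")) {
    abort(sprintf("Unknown plant mode '%s'.", mode), class = "basinrank_domain_error")
  }
  basins <- tables$basins; subbasins <- tables$subbasins
  in_region <- basins$basin_id[basins$region_id == region]
  if (!length(in_region)) {
    abort(sprintf("Region '%s' not found.", region), class = "basinrank_domain_error")
  }
  plants <- attr(tables, "plants") %||% list()
  taken <- vapply(plants, `[[`, character(1), "basin_id")
  candidates <- setdiff(sort(in_region), taken)
  if (!length(candidates)) {
    abort(sprintf("No unplanted basin left in region '%s'.", region),
          class = "basinrank_domain_error")
  }
  n_sub_by <- table(subbasins$basin_id)
  target <- if (mode == "impact_dominant") {
    candidates[1]
  } else {
    cnt <- as.integer(n_sub_by[candidates])
    candidates[order(-cnt, candidates)][1]
  }
  b_row <- which(basins$basin_id == target)
  s_rows <- which(subbasins$basin_id == target)
  backup <- list(basin_id = target, mode = mode,
                 basin_row = basins[b_row, ], subbasin_rows = subbasins[s_rows, ])

  # Plant strictly beyond the observed extremes (1% past them, capped at each
  # variable's hard support) so the plant holds every relevant rank alone:
  # with the strictly-less percent-rank convention, a value merely tied with
  # the roster maximum would not reach rank 1.
  upper_cap <- c(pct_waterbodies = 100, biotic_index = 1, tile_fraction = 1)
  beyond_max <- function(x, col) {
    hi <- max(x, na.rm = TRUE) * 1.01
    if (col %in% names(upper_cap)) min(hi, upper_cap[[col]]) else hi
  }
  below_min <- function(x) min(x, na.rm = TRUE) * 0.99

  for (col in .br_receptor_cols) {
    basins[[col]][b_row] <- beyond_max(basins[[col]], col)
  }
  n <- length(s_rows)
  if (mode == "impact_dominant") {
    level_cols <- c("stream_N_vwm", "stream_P_vwm", "gw_shallow_no3", "gw_ps_no3",
                    "fertmanure_N", "fertmanure_P", "wwtp_N", "wwtp_P", "septic_N")
    for (col in level_cols) {
      subbasins[[col]][s_rows] <- beyond_max(subbasins[[col]], col)
    }
  } else {
    if (n < 4L) {
      warn(sprintf("variability_dominant plant in '%s' has only %d subbasin(s); the planted interquartile range may not reach the roster-wide extreme.",
                   target, n))
    }
    lo_half <- seq_len(ceiling(n / 2))
    for (col in .br_spread_cols) {
      lo <- below_min(subbasins[[col]])
      hi <- beyond_max(subbasins[[col]], col)
      v <- rep(hi, n); v[lo_half] <- lo
      subbasins[[col]][s_rows] <- v
    }
    amp <- max(abs(c(subbasins$resid_N, subbasins$resid_P)), na.rm = TRUE) * 1.01
    signs <- rep_len(c(-1, 1), n)
    subbasins$resid_N[s_rows] <- signs * amp
    subbasins$resid_P[s_rows] <- -signs * amp
  }
  plants[[length(plants) + 1L]] <- backup
  out <- list(basins = basins, subbasins = subbasins)
  attr(out, "plants") <- plants
  out
}

#' Restore tables modified by [plant_extreme()]
#'
#' @param tables Tables returned by [plant_extreme()].
#' @return The tables with every planted basin's original rows restored and
#'   the `plants` attribute removed.
#' @export
unplant <- function(tables) {
  plants <- attr(tables, "plants")
  if (is.null(plants)) return(tables)
  basins <- tables$basins; subbasins <- tables$subbasins
  for (pl in rev(plants)) {
    basins[basins$basin_id == pl$basin_id, ] <- pl$basin_row
    subbasins[subbasins$basin_id == pl$basin_id, ] <- pl$subbasin_rows
  }
  list(basins = basins, subbasins = subbasins)
}
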