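# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation.

# Inclusive linear-interpolation percentile, written straight from the
# definition: h = 1 + p * (n - 1) over the sorted values.
brute_percentile <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

# Percent rank by pairwise comparison: fraction of the other values each
# element strictly exceeds.
brute_percent_rank <- function(values) {
  n <- length(values)
  if (n == 1L) return(1)
  vapply(values, function(x) sum(values < x), numeric(1)) / (n - 1)
}

# All multisets of size n over an alphabet, as rows of a matrix.
all_multisets <- function(n, alphabet) {
  grid <- as.matrix(expand.grid(rep(list(alphabet), n)))
  unique(t(apply(grid, 1L, sort)))
}

# A tiny handmade roster: 3 basins in 2 regions, 9 subbasins.
tiny_tables <- function() {
  basins <- tibble::tibble(
    basin_id = c("A", "B", "C"),
    region_id = c("r1", "r1", "r2"),
    area_km2 = c(1000, 2000, 1500),
    pop_served_per_km2 = c(10, 40, 25),
    pct_waterbodies = c(1, 5, 2.5),
    biotic_index = c(0.2, 0.8, 0.5),
    delivered_N_yield = c(100, 400, 250),
    delivered_P_yield = c(10, 40, 25)
  )
  subbasins <- tibble::tibble(
    huc08_id = paste0("h", 1:9),
    basin_id = rep(c("A", "B", "C"), each = 3),
    stream_N_vwm = c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 0.1, 1.0, 4.0),
    stream_P_vwm = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.01, 0.10, 0.40),
    fertmanure_N = c(500, 600, 700, 2000, 2100, 2200, 100, 1000, 3000),
    fertmanure_P = c(50, 60, 70, 200, 210, 220, 10, 100, 300),
    wwtp_N = c(5, 6, 7, 20, 21, 22, 1, 10, 30),
    wwtp_P = c(1, 1.2, 1.4, 4, 4.2, 4.4, 0.2, 2, 6),
    septic_N = c(10, 12, 14, 40, 42, 44, 2, 20, 60),
    tile_fraction = c(0.1, 0.12, 0.14, 0.4, 0.42, 0.44, 0.01, 0.2, 0.6),
    runoff = c(0.2, 0.22, 0.24, 0.5, 0.52, 0.54, 0.05, 0.3, 0.8),
    gw_shallow_no3 = c(1, 1.2, 1.4, 4, 4.2, 4.4, 0.2, 2, 6),
    gw_ps_no3 = c(0.5, 0.6, 0.7, 2, 2.1, 2.2, 0.1, 1, 3),
    resid_N = c(-10, 5, 8, -20, 15, 25, -2, 3, 40),
    resid_P = c(4, -6, 9, -12, 18, -22, 1, -3, 35)
  )
  list(basins = basins, subbasins = subbasins)
}
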