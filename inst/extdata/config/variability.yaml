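# Variability approach: where can nutrient-process studies learn the most?
# 20 variables in four categories. Variable ranks are computed within each
# hydrologic region (or across the full roster for national scoring); each
# category score is the weighted rank sum divided by the category's total
# weight, so every un-penalized category score lies in [0, 1]. Interquartile
# ranges (75th minus 25th percentile of HUC08 values) measure spread; minimum
# stream concentrations rank descending because the strongest biological
# response occurs at low nutrient concentrations; model-residual magnitudes
# rank ascending because poorly predicted basins have the most to teach.
approach: variability
category_normalization: by_weight_sum
category_weights:
  water_quality: 1.0
  factor: 1.0
  receptor: 0.5
  accuracy: 0.5
eligibility:
  enabled: true
  top_k: 4
  penalty: 5.0
  scope: region
variables:
  - name: stream_N_range
    category: water_quality
    source_column: stream_N_vwm
    level: subbasin
    aggregation: iqr_range
    transform: log10_floored
    direction: ascending
    weight: 0.5
  - name: stream_P_range
    category: water_quality
    source_column: stream_P_vwm
    level: subbasin
    aggregation: iqr_range
    transform: log10_floored
    direction: ascending
    weight: 0.5
  - name: stream_N_min
    category: water_quality
    source_column: stream_N_vwm
    level: subbasin
    aggregation: minimum
    transform: log10_floored
    direction: descending
    weight: 0.5
  - name: stream_P_min
    category: water_quality
    source_column: stream_P_vwm
    level: subbasin
    aggregation: minimum
    transform: log10_floored
    direction: descending
    weight: 0.5
  - name: fertmanure_N_range
    category: factor
    source_column: fertmanure_N
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 0.5
  - name: fertmanure_P_range
    category: factor
    source_column: fertmanure_P
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 0.5
  - name: wwtp_N_range
    category: factor
    source_column: wwtp_N
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 0.5
  - name: wwtp_P_range
    category: factor
    source_column: wwtp_P
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 0.5
  - name: septic_N_range
    category: factor
    source_column: septic_N
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 1.0
  - name: tile_fraction_range
    category: factor
    source_column: tile_fraction
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 1.0
  - name: runoff_range
    category: factor
    source_column: runoff
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 1.0
  - name: gw_shallow_no3_range
    category: factor
    source_column: gw_shallow_no3
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 0.5
  - name: gw_ps_no3_range
    category: factor
    source_column: gw_ps_no3
    level: subbasin
    aggregation: iqr_range
    direction: ascending
    weight: 0.5
  - name: resid_N_magnitude
    category: accuracy
    source_column: resid_N
    level: subbasin
    aggregation: mean_abs
    direction: ascending
    weight: 1.0
  - name: resid_P_magnitude
    category: accuracy
    source_column: resid_P
    level: subbasin
    aggregation: mean_abs
    direction: ascending
    weight: 1.0
  - name: pop_served
    category: receptor
    source_column: pop_served_per_km2
    level: basin
    aggregation: none
    direction: ascending
    weight: 1.0
  - name: pct_waterbodies
    category: receptor
    source_column: pct_waterbodies
    level: basin
    aggregation: none
    direction: ascending
    weight: 1.0
  - name: biotic_index
    category: receptor
    source_column: biotic_index
    level: basin
    aggregation: none
    direction: ascending
    weight: 1.0
  - name: delivered_N_yield
    category: receptor
    source_column: delivered_N_yield
    level: basin
    aggregation: none
    direction: ascending
    weight: 0.5
  - name: delivered_P_yield
    category: receptor
    source_column: delivered_P_yield
    level: basin
    aggregation: none
    direction: ascending
    weight: 0.5
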