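# basinrank

Quantitative prioritization of large river basins for nutrient (nitrogen and
phosphorus) water-quality studies. The package is aimed at monitoring-network
designers and water-quality modelers who must decide, from a national roster
of HUC04-sized candidate basins grouped into hydrologic regions, (a) where
nutrient problems are worst and (b) where intensive process studies would
teach the most.

Two weighted percent-rank composites answer those questions:

- **Impact approach** (14 variables) — favors basins with high stream and
  groundwater nutrient concentrations, large anthropogenic sources, and
  exposed receptors. It identifies where management action would matter most.
- **Variability approach** (20 variables) — favors basins whose HUC08
  subbasins span wide ranges of concentrations and driving factors, include
  low-concentration streams (where biological response is steepest), and are
  poorly predicted by current watershed models. It identifies the best study
  sites.

## The method

Every variable *v* is reduced to one value per basin (directly for
basin-level variables; by the median, the interquartile range
`p75 − p25` of the HUC08 values, the minimum, or the mean absolute model
residual for subbasin-level variables, optionally after a base-10 log
transform) and normalized to a unit-interval percent rank across the ranking
scope with the spreadsheet convention

```
rank(x) = #{values strictly below x} / (n − 1)
```

so 0 is the least and 1 the most favorable basin, with tied values sharing a
rank. Weighted ranks are combined into category scores, e.g. the impact
water-quality score

```
WQ = (1.5·rank(shallow GW nitrate) + 0.5·rank(GW nitrate at public-supply depth)
      + 1.0·rank(stream N) + 1.0·rank(stream P)) / 4
```

and category scores into the overall scores

```
Impact      = 1.0·WQ + 1.0·Source + 1.0·Receptor
Variability = 1.0·WQ + 1.0·Factors + 0.5·Receptor + 0.5·Accuracy
```

Impact variable ranks always span the full roster; variability ranks span
each hydrologic region (or the full roster for national scoring), and a
basin outside its region's top four water-quality scores has 5 points
subtracted from that score, which removes it from contention for the
regional top spot. Overall scores are then ranked regionally and nationally;
the top two basins per region form the priority set.

## Worked example

```r
library(basinrank)

roster <- generate_roster(synthetic_config(seed = 1))  # 163 basins, 18 regions
imp <- run_impact(roster$basins, roster$subbasins)
var <- run_variability(roster$basins, roster$subbasins, scope = "region")

dplyr::arrange(imp, national_ordinal)[1:5, c("basin_id", "region_id",
  "water_quality", "source", "receptor", "overall", "national_ordinal")]
#>   basin_id region_id water_quality source receptor overall national_ordinal
#> 1 R02_B05  R02               0.852  0.923    0.398    2.17                1
#> 2 R02_B09  R02               0.780  0.832    0.487    2.10                2
#> 3 R15_B03  R15               0.895  0.640    0.562    2.10                3
#> 4 R05_B09  R05               0.681  0.926    0.444    2.05                4
#> 5 R02_B06  R02               0.798  0.860    0.389    2.05                5
```

Basin `R02_B05` tops the impact ranking: it sits at the 85th water-quality,
92nd source, and 40th receptor percentile-score of the roster, summing to an
overall score of 2.17 out of a possible 2.8. Selecting and comparing
priority basins:

```r
select_top_n(var, 2)     # 36 priority basins, 2 per region
compare_top_picks(imp, var)
#> [1] 17
```

Here 17 of the 18 regions get a different top basin from the two approaches —
the impact winner is typically a uniformly high-concentration basin, the
variability winner one whose subbasins span clean-to-impacted gradients.
`summarize_categories()` tabulates per-region category-score distributions,
and `write_rankings()` / `load_tables()` move rosters and results through
documented CSV schemas. A thin command-line wrapper lives at
`inst/scripts/basinrank.R`.

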