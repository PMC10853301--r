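---
title: "Ranking river basins for nutrient studies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking river basins for nutrient studies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(basinrank)
```

## The two ranking models

`basinrank` scores HUC04-sized candidate basins, grouped into hydrologic
regions, with two weighted percent-rank composites.

The **impact approach** asks where nutrient problems are worst. Fourteen
variables enter three categories:

* *water quality* — median HUC08 stream total-N and total-P
  volumetrically-weighted-mean concentrations (mg/L), and median predicted
  nitrate in shallow groundwater (weight 1.5) and at public-supply depth
  (weight 0.5), in mg/L as N;
* *source* — fertilizer-plus-manure N and P, wastewater N and P, and septic
  N yields (kg/km²/yr), each weight 1;
* *receptor* — population served per km², percent open water, a biotic
  index (likelihood a stream is *not* in good biological condition),
  and delivered N and P yields to distant receiving waters (weight 0.5 each).

The **variability approach** asks where process studies would learn the
most. Twenty variables enter four categories: the interquartile range
(75th minus 25th percentile of the HUC08 values, an outlier-resistant
spread) of log-transformed stream N and P concentrations plus their
*minimum* concentrations, ranked descending because the steepest biological
response occurs at low concentrations (*water quality*); interquartile
ranges of the nine factors driving concentrations — source yields, tile-drain
fraction, runoff, groundwater nitrate at two depths (*factor*); mean
absolute watershed-model load residuals in log-space percent, ranked
ascending because poorly predicted basins have the most to teach
(*accuracy*); and the same five receptor variables (*receptor*).

Both composites share one arithmetic core. Each basin-level variable value
is percent-ranked across its scope with the spreadsheet convention
`rank(x) = #{values < x}/(n − 1)` (ties share a rank; see "Numerical
choices"). Category scores are weighted rank sums divided by a normalizer,
and overall scores are

* impact: `1.0·WQ + 1.0·Source + 1.0·Receptor`, ranks always computed
  across the **full roster**, even for regional reporting, so that small
  within-region differences cannot dominate;
* variability: `1.0·WQ + 1.0·Factors + 0.5·Receptor + 0.5·Accuracy`, ranks
  computed **within each region** (or across the roster for national
  scoring), the half weights reflecting that receptor exposure and
  single-model accuracy should inform but not drive site selection.

Before the final regional variability ranking, any basin whose
water-quality category score is strictly below its region's fourth-highest
is docked 5 points on that score. Since the maximum attainable overall
score is 3, the penalty is an eligibility rule: the regional winner must
come from the water-quality top four, guaranteeing the selected basin
actually contains the concentration gradient the approach exists to find.
Ties with the fourth-highest score leave all tied basins eligible, and
regions with four or fewer basins are untouched.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| variable weights | Table-specified (0.5/1/1.5) | — | Paired N/P variables share importance; shallow groundwater outweighs public-supply depth because shallow aquifers feed streams and untreated domestic wells |
| `category_normalization` | impact: variable count; variability: weight sum | — | Reproduces the published `/4` water-quality divisor for impact; puts every variability category on `[0, 1]` |
| `eligibility$top_k` | 4 | basins | Size of the regional water-quality short list |
| `eligibility$penalty` | 5 | score points | Any value above the maximum overall score (3) is equivalent; 5 makes penalized scores visibly negative |
| `scope` (variability) | `"region"` | — | Regional studies are the primary use; `"national"` ranks across the roster without the penalty |
| `select_top_n(n)` | 2 | basins/region | Two per region turns an 18-region roster into 36 priority basins |

A consequence of normalizing the impact receptor category by its five
variables while its weights sum to four is that the receptor score spans
`[0, 0.8]`; with all three categories maximal the impact overall score is
2.8, not 3.0. Dividing by the weight sum instead is available through
`category_normalization = "by_weight_sum"` but is not the default, because
the count divisor is what the published water-quality equation shows.
Similarly, the variability overall score combines the category *scores*
directly; re-ranking category scores before weighting would discard
magnitude information and is not done.

## The synthetic roster generator

`generate_roster()` emulates the statistical structure the rankings
assume, not any real geography: 18 regions holding 163 basins (the study
roster dimensions), each basin with 4–12 HUC08 subbasins. Source yields and
concentrations are log-normal with region-level locations and a shared
basin-level random effect (hierarchical positive skew); tile-drain fraction
and biotic index are Beta; runoff is Gamma; load residuals are signed
Normal percent errors in log space with region-specific spread. Stream and
groundwater concentrations blend a standardized local-source signal with
independent noise under a coupling coefficient in `[0, 1]` (default 0.6),
so the source-to-water-quality association present in real rosters is
reproducible in expectation and vanishes at coupling 0. All draws descend
deterministically from one seed through per-region substreams.

What the generator does **not** emulate: spatial autocorrelation between
neighboring basins, network routing (each HUC08 is exchangeable within its
basin), calibration of the marginals to the real data release, and
real-world data gaps. Passing tests on synthetic rosters therefore
demonstrate the correctness of the ranking arithmetic and its invariants —
not that the package reproduces the published basin identities, which
requires the study's data release as input.

`plant_extreme()` turns the generator into an oracle: an
`impact_dominant` plant receives values strictly beyond the roster maximum
of all 14 impact variables and must rank first nationally; a
`variability_dominant` plant receives the widest possible subbasin spreads,
the lowest minimum concentrations, and the largest residual magnitudes, and
must rank first in its region. The 1% margin past the observed extremes
matters: under the strictly-less rank convention a value merely *tied* with
the maximum ranks `(n−2)/(n−1)`, not 1.

## Numerical choices

* **Percentile convention.** Inclusive linear interpolation
  (`h = 1 + p(n−1)`; `stats::quantile` type 7), the spreadsheet convention,
  so the minimum and maximum are exactly the 0th and 100th percentiles.
* **Percent rank.** `#{strictly below}/(n − 1)` with ties sharing a rank —
  the spreadsheet PERCENTRANK rule evaluated at array members, needing no
  interpolation. A single-basin scope returns rank 1: a lone basin is
  trivially top. Non-finite inputs are domain errors, never silently
  dropped.
* **Log transform of concentrations.** Base 10. Zeros are floored to
  `log10` of half the smallest positive value in the basin's multiset,
  keeping zero-concentration subbasins rankable and strictly below every
  observed value; an all-zero multiset is returned unchanged with a
  warning.
* **Residual statistic.** Mean of absolute signed log-space residuals:
  predictability is about error magnitude, not direction.
* **Tie-breaking of ordinals.** Exact overall-score ties break by basin id,
  lexicographically, so output files are reproducible across platforms.
* **Missing values.** A basin missing a variable keeps its other scores:
  the missing rank is dropped and the category normalizer shrinks
  accordingly (with a warning), rather than scoring the gap as "least
  impacted". A basin whose subbasins are entirely absent from the subbasin
  table is a referential error.
* **Degenerate spreads.** A single-subbasin basin has interquartile range 0
  for every range variable — logged as a warning, not an error, since the
  basin remains rankable on its other variables.

## Verification strategy and problem sizes

The test suite checks the arithmetic against independent brute-force
oracles (pairwise-comparison percent ranks on every multiset of size ≤ 8
over a four-letter alphabet; hand-rolled interpolation percentiles on
random multisets), property invariants (weak monotonicity of every score in
any single ascending variable, order invariance, descending/ascending
symmetry, translation and scale behavior of the interquartile range), and
end-to-end guarantees on synthetic rosters (planted extremes recovered at
ordinal 1 across 20 seeded 163-basin rosters; every regional variability
winner inside its region's water-quality top four; byte-identical repeated
runs). Full-roster sizes (163 basins, ~1300 subbasins) are used throughout
because the pipeline is vectorized and each run takes well under a second,
so there is no need to test at reduced scale.

## Limitations

Rankings inherit every limitation of their inputs: modeled concentrations
and residuals come from upstream watershed and groundwater models, and the
variability measured here is variability *at the HUC08 scale* — a different
subbasin delineation would change the spread statistics. Percent ranks
compress real differences in heavily tied or narrow-range variables, and
with `n − 1` in the denominator a tied maximum does not reach rank 1. The
two approaches are deliberately not blended into one score; they answer
different questions and are meant to be consulted in sequence.
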