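# cropSCS

Climate change is shifting where food crops can grow. **cropSCS** quantifies
that shift with the Safe Climatic Space (SCS) approach: a crop's climatic
niche is the region of climate space occupied today by the grid cells
producing the top 95 % of its tonnage, described with Holdridge life-zone
parameters — annual precipitation, biotemperature, potential
evapotranspiration (PET = 58.93 × biotemperature), aridity (PET /
precipitation) and an annual frost indicator. Projecting future climate at
global warming levels (1.5–4 °C) across a GCM ensemble, the package asks
which croplands fall out of (or into) each crop's niche, and answers with
three families of results:

1. **Risk to current production** — per cell, the lowest warming level that
   pushes ≥ 25 % (or 50 %/75 %) of current production outside the
   crop-specific SCSs, with regional cropland-area summaries; and per
   crop/crop group, the share of production outside the SCS with ensemble
   median and interquartile spread.
2. **Cropland area within each SCS** — net, gained and lost hectares as
   percentages of the baseline within-SCS area (net = gain − loss holds
   identically).
3. **Potential crop diversity** — per cell, how many crops' niches contain
   the local climate, how that count changes with warming, and where
   "cropland with emerging climatic potential" appears.

It is aimed at agro-climatic and food-security researchers who want the SCS
machinery as tested, reusable building blocks rather than a one-off script.
Inputs are ordinary gridded monthly climatologies (minimum/maximum
temperature, precipitation) plus per-crop production and cropland-area
rasters; everything is exchanged in plain-text formats (ESRI ASCII grid,
CSV, JSON). A deterministic synthetic-world generator with known true niches
makes the entire pipeline testable without downloading any archive.

## Worked example

```r
library(cropSCS)

world <- generateWorld(worldConfig(seed = 1))   # 60 x 120 grid, 6 crops, 4 GCMs
res   <- runPipeline(world)

res$scs[["crop01"]]
#> SCSDefinition for crop 'crop01': 37 occupied climate bins
#>   captured production share: 0.9501 (1543 major cells, binsPerClass = 2)
```

The crop's niche is 37 occupied bins in (precipitation × biotemperature ×
aridity × frost) space, delineated from the 1543 cells that carry 95.01 % of
its production — the realized share is always ≥ the nominal 95 % because the
cell crossing the threshold is included.

```r
subset(res$cropNet, level == 2)
#>      crop level  netMedian     netP25     netP75
#> 7  crop01     2  -9.472190  -9.516205  -9.421648
#> 8  crop02     2  -4.455454  -4.468878  -4.445782
#> 9  crop03     2  -6.834338  -6.909353  -6.751421
#> 10 crop04     2 -16.143682 -16.387521 -16.022030
#> 11 crop05     2 -19.293687 -19.313052 -19.127568
#> 12 crop06     2 -11.643244 -11.674493 -11.570250
```

Under 2 °C of warming every synthetic crop loses cropland within its niche —
the ensemble-median net change ranges from −4.5 % to −19.3 % of the baseline
within-SCS area (columns are the median and 25th/75th percentiles across the
pseudo-GCMs).

```r
subset(res$regionalRisk, region == "low latitude")
#>         region level  areaShare
#> 1 low latitude   1.5 0.09832345
#> 2 low latitude   2.0 0.13994092
#> 3 low latitude   3.0 0.27513986
#> 4 low latitude   4.0 0.50022748
```

In the low-latitude band, 9.8 % of cropland area is at "considerable risk"
(≥ 25 % of local production outside the niches) already at 1.5 °C, rising to
50 % at 4 °C — the equator-side niche edge is where uniform warming bites
first, the same latitudinal asymmetry the method is designed to expose.
`res$groupShares`, `res$diversity` and `res$riskMaps` hold the per-group
production shares, the potential-diversity category fields with regional and
elevation-band summaries, and the lowest-risk-level maps.

## Package tour

- `worldConfig()` / `generateWorld()` / `groundTruthReport()` — synthetic
  world with exposed ground truth.
- `computeHLZParams()`, `biotemperature()`, `annualPET()`, `aridityIndex()`,
  `frostIndicator()`, `hlzClassify()` — Holdridge parameters and the
  38-zone classifier.
- `warmingLevelTable()`, `interpolateWarmingLevel()` — warming-level
  interpolation between period climatologies.
- `delineateSCS()`, `scsMembership()`, `selectMajorCells()`,
  `selectMarginalCells()` — niche delineation and membership.
- `projectMembership()`, `majorityVote()`, `ensembleQuantiles()` — ensemble
  consensus.
- `cellShareOutside()`, `lowestRiskLevel()`, `productionOutsideByCrop()`,
  `aggregateGroupShares()` — production-risk indicators.
- `gainLossRatios()`, `groupAreaStats()`, `potentialDiversity()`,
  `classifyDiversityChange()`, `zonalCategorySummary()` — area and
  diversity change.
- `runPipeline()` — the orchestrated end-to-end workflow with provenance.

See `vignettes/safe-climatic-space.Rmd` for the model, parameter and design
documentation.
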