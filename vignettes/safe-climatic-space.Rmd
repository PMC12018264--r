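---
title: "Safe Climatic Spaces: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe Climatic Spaces: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropSCS)
```

## The model

A crop's **Safe Climatic Space (SCS)** is its empirical climatic niche: the
region of climate space occupied today by the grid cells that host the crop's
major production. cropSCS works in the Holdridge life-zone parameter space,
four coordinates computed from monthly climatologies:

- **annual precipitation** `P` [mm/yr]: the sum of the twelve monthly means;
- **biotemperature** `T_bio` [°C]: monthly mean temperatures clamped below at
  0 °C, summed and divided by 12;
- **potential evapotranspiration** `PET = 58.93 × T_bio` [mm/yr], the
  Holdridge estimate;
- **aridity** `PET / P` (dimensionless; > 1 means water demand exceeds
  supply);

plus a binary **frost indicator** (TRUE where no month's minimum temperature
is at or below 0 °C), which is what separates temperate from subtropical
life zones. Monthly mean temperature is estimated as the midpoint of monthly
minima and maxima and bias-corrected, additively per cell and month, against
a reference period in which all three temperature statistics are available.

The space is discretized into log2-spaced bins aligned with the Holdridge
class geometry (precipitation classes doubling from 62.5 mm/yr,
biotemperature belts doubling from 1.5 °C, aridity provinces doubling across
2^-5..2^8), each class split into `binsPerClass` sub-bins (default 2). The
SCS of a crop is then simply the *set of occupied bins*: the bins containing
at least one cell of the crop's major-production prefix — the smallest set
of cells, in descending production order, that carries 95 % of the crop's
tonnage. No convex hull, kernel density or distribution model is fitted; the
envelope is the occupied-bin set and nothing more. Because the result
depends on the resolution, `binsPerClass` is recorded in every definition's
provenance and should be reported alongside any result.

Future climates are represented at **global warming levels** (1.5, 2, 3,
4 °C above pre-industrial). Each level is assigned the first scenario to
cross it and the climate is interpolated linearly, cell by cell, between the
two period climatologies whose centre years `x0 < x1` bracket the crossing
year `x`:

    Y = (Y0 (x1 - x) + Y1 (x - x0)) / (x1 - x0)

The shipped table (`warmingLevelTable()`) pairs 1.5 °C with SSP1-2.6
(x = 2033, x0 = 2031, x1 = 2051), 2 °C with SSP2-4.5 (2053; 2051, 2071),
3 °C with SSP3-7.0 (2076; 2071, 2091) and 4 °C with SSP5-8.5 (2085; 2071,
2091); the later levels' centre years follow from the future periods
available for each scenario, and every row can be overridden. Membership
under a level is evaluated per ensemble member (eight CMIP6 GCMs in the
motivating application) and a cell counts as *within* the SCS by consensus
iff at least `ceil(n/2)` members say so — "at least half", read inclusively,
so 4 of 8 suffices.

From memberships the package derives three families of results:

1. **Risk to current production.** Per cell, the production-weighted share
   of the (food-crop) production outside the respective SCSs, using
   consensus membership; then the lowest warming level at which that share
   reaches a threshold (25 % by default — "considerable risk" — with 50 %
   and 75 % as sensitivity settings; cells never crossing are reported as
   such). Separately, per crop, the share of total production outside the
   SCS is computed per ensemble member and summarized by the median and
   25th/75th percentiles; crop-group and all-crop figures divide the summed
   member-crop statistics (in tons) by the summed reference production.
2. **Cropland area within the SCS.** On the total-cropland extent,
   `A_warming = A_baseline + A_gain − A_loss` in physical hectares; net
   change is `(A_warming − A_baseline)/A_baseline × 100 %` and the
   gain/loss ratios are `A_change/A_baseline × 100 %`, so net = gain − loss
   holds identically.
3. **Potential crop diversity.** Per cell, the count of crops whose SCS
   contains the cell's climate, irrespective of where they are grown; its
   change from baseline is binned in 25-point percentage categories, with
   −100 % and "no change" pulled out, and two special categories where the
   baseline count is zero: *cropland with emerging climatic potential*
   (at least one SCS arrives under warming) and *marginal in baseline and
   outside SCS under warming level*. Summaries weight by physical cropland
   hectares within regions, latitude bands and elevation bands.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `share` (delineation) | 0.95 | production prefix defining major cells; the crossing cell is included, so the realized share is ≥ the nominal one |
| marginal share | 0.05 | complement rule for marginal production (lowest 5 % of tonnage) |
| `binsPerClass` | 2 | sub-bins per Holdridge class per axis |
| `riskThresholds` | 0.25, 0.50, 0.75 | production share defining risk |
| aridity cap | 2^8 | finite aridity where precipitation is 0 but PET > 0 |
| `biotempCap` | none | optional monthly biotemperature clamp (some Holdridge variants cap at 30 °C) |
| elevation bands | <500, 500–1500, 1500–2500, >2500 m | zonal summary bands |
| vote rule | ceil(n/2) | inclusive "at least half" consensus |

## Numerical choices

- **Biotemperature denominator.** The positive-clamped monthly sum is
  divided by 12, not by the number of positive months. This is the
  convention of the Holdridge framework itself and the only choice that
  keeps `PET = 58.93 × T_bio` consistent with summing monthly PET values;
  the alternative reading would make a single warm month in a polar cell
  count as a 20 °C climate.
- **Frost boundary.** Frost-free requires *strictly* positive monthly
  minima; an exact 0 °C month is frosty.
- **Zero precipitation.** Aridity is capped at 2^8 (beyond the driest
  class edge) instead of infinite, keeping the binning finite; a
  zero-PET, zero-precipitation cell has aridity 0.
- **Bin edges.** All class intervals are half-open `[low, high)`; values
  below the first or at/above the last edge fall into open-ended outer
  bins, so every finite climate maps to exactly one bin and the 38-zone
  classifier (`hlzClassify()`, edge table shipped as a versioned CSV)
  emits exactly 38 labels over the full domain.
- **Interpolating the frost flag.** The binary indicator is interpolated
  numerically with the same linear rule as the continuous parameters and
  re-thresholded at ≥ 0.5, restoring binarity.
- **Ties in the production ranking** are broken by row-major cell order, so
  delineation is deterministic and invariant to how the raster was stored.
- **Percentiles** across ensemble members use linear interpolation between
  order statistics (type 7); the method is recorded in run provenance.
- **Degenerate inputs.** Zero-baseline areas make percentage changes
  undefined (NA, reported as such); all-zero production rejects delineation
  with an informative error; misaligned grids are a hard error everywhere —
  the package never resamples silently.

## The synthetic world

`generateWorld()` builds the test bed every downstream stage runs on: a
single-hemisphere grid (row 1 at the equator) with monthly mean temperature
= latitudinal gradient + poleward-growing seasonal sinusoid + white noise
(sd 0.3 °C), a fixed 8 °C diurnal range so the min/max midpoint is exact,
and log-normal monthly precipitation (log-sd 0.05) around a latitudinal band
structure — wet intertropical belt (~2400 mm/yr), dry subtropics
(~450 mm/yr), moderate storm-track mid-latitudes (~950 mm/yr), dry poles —
so aridity varies across the full Holdridge range. Crop production is drawn
log-normally on the cells whose baseline parameters fall inside each crop's
known true niche (a box in biotemperature × precipitation with an aridity
ceiling); 2 % of each crop's tonnage is scattered outside the niche to
exercise the lowest-5 % marginal rule, and a few fallow cells carry cropland
area with no production. Pseudo-GCM futures equal the baseline plus the
level's uniform delta (1.5/2/3/4 °C) and a precipitation scale factor
(1 − 0.02 × delta, mild drying) plus per-member seeded noise, which makes
majority-vote behaviour predictable. The whole bundle is bit-identical under
a fixed seed.

What the generator does *not* emulate: circulation, ENSO-like variability,
coastlines and orographic climate, spatially correlated GCM disagreement,
and any socio-economic structure in where crops are grown. Passing tests on
this world therefore demonstrate the *correctness of the machinery* —
parameter arithmetic, envelope logic, vote and aggregation rules, exact
identities — and the qualitative response (equatorial losses, poleward
gains under uniform warming), not the magnitude of any real-world result.

```{r, eval = FALSE}
world <- generateWorld(worldConfig(seed = 1))   # 60 x 120, 6 crops, 4 GCMs
res <- runPipeline(world)
res$cropNet          # per-crop net % change in cropland within the SCS
res$regionalRisk     # share of regional cropland at considerable risk
```

The default problem size — a 60 × 120 grid, 6 crops, 4 pseudo-GCMs, 4
warming levels — runs the full pipeline in a few seconds and is the scale
used throughout the test suite; the machinery is resolution-agnostic and
identical code paths serve larger grids.

## Design decisions made where the design was open

- **Discretization of the climate space.** The SCS literature maps
  production into the three-parameter space without stating a bin
  resolution. We align bins with the Holdridge class structure (the
  framework the concept cites) and expose `binsPerClass`; envelopes are
  monotone under coarsening (a coarser binning never shrinks the member
  set), which the suite asserts.
- **"Marginal in baseline" is defined climate-side** (baseline potential
  diversity count 0) rather than by production rank. Major-production cells
  are within their own crop's SCS by construction, so baseline-zero cells
  host at most marginal production — this makes the category computable
  from memberships alone; the production-side reading stays available via
  `selectMarginalCells()`.
- **Open-ended top diversity bin.** A percentage-change bin system capped
  at +100 % cannot be exhaustive (a baseline count of 1 rising to 3 is
  +200 %), so the top positive category is "> +75 %"; the legend records
  this.
- **Area weighting** always uses the supplied physical cropland hectares,
  never geometric cell area — no geodesy enters the package.
- **Consensus is computed independently per warming level**; a cell may
  re-enter an SCS at a higher level. No continuity constraint is imposed.
- **Regional aggregation of the production-risk indicator** restricts
  production to the region before normalization, reusing the same
  per-member machinery as the global figures.
- **Plain-text formats.** Fields are exchanged as ESRI ASCII grids, monthly
  climatologies as long-format CSV, SCS definitions and provenance as JSON.
  Alignment is checked on load (dimensions, origin, cell size); mismatches
  are hard errors naming the offending file.

## Known limitations

- The envelope is purely climatic: no soils, management, CO2 fertilization,
  prices, or crop calendars (a growing-season variant is out of scope), and
  no yield model — membership is binary.
- The Holdridge PET is the only PET formulation offered.
- Niches are held fixed ("climatically fixed" SCS): adaptation through new
  varieties or practices is outside the model.
- Grids must be pre-aligned; the package neither regrids nor gap-fills.
- With few ensemble members the inclusive majority rule is coarse (2 of 2,
  2 of 3); the motivating application uses eight members.
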