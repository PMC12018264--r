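#' @include synthetic.R projection.R risk.R diversity.R
NULL

#' Provenance record for a pipeline run
#'
#' Captures the configuration hash, package version and the methodological
#' decisions in force (binning resolution, percentile method, vote rule) so
#' that two runs are comparable: digests change iff an input or decision
#' changes. No wall-clock content enters the record, keeping reruns
#' byte-identical.
#'
#' @param config any serializable configuration object
#' @param binning the [ClimateBinning-class] in force
#' @return list
#' @export
provenanceRecord <- function(config, binning) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  list(configHash = unname(tools::md5sum(tmp)),
       package = "cropSCS",
       version = as.character(utils::packageVersion("cropSCS")),
       decisions = list(binsPerClass = binning@binsPerClass,
                        percentileMethod = "linear interpolation (type 7)",
                        voteRule = "within iff >= ceil(n/2) members within",
                        aridityZeroPrecipCap = 2^8,
                        frostConvention = "frost-free iff all monthly minima > 0"))
}

#' Run the full Safe Climatic Space analysis on a world bundle
#'
#' End-to-end workflow: Holdridge parameters for baseline and for every
#' (warming level, ensemble member); SCS delineation per food crop from
#' baseline major-production cells; membership cubes on the total-cropland
#' extent; the two production-risk indicators; cropland-area change within
#' each SCS with group aggregation; and potential-diversity change with its
#' category system and zonal summaries. Deterministic: rerunning with the
#' same world gives identical results.
#'
#' @param world a [SyntheticWorld-class] (or any object with the same slots)
#' @param binning a [ClimateBinning-class]
#' @param majorShare major-production share for delineation (default 0.95)
#' @param riskThresholds production-share thresholds for the lowest-risk
#'   indicator (default 0.25, 0.50, 0.75)
#' @return list of results (see Details) plus a provenance record
#' @details Components: `scs` (per-crop definitions), `baselineParams`,
#'   `membership` (per-level [MembershipCube-class]), `baselineConsensus`,
#'   `riskMaps` (per threshold), `regionalRisk`, `productionOutside` (crop x
#'   level quantiles), `groupShares` (per level), `areaChanges` (crop x gcm x
#'   level components), `cropNet` (crop x level median net %), `groupArea`
#'   (per level), `diversity` (counts, categories, zonal summaries),
#'   `provenance`.
#' @export
runPipeline <- function(world, binning = climateBinning(), majorShare = 0.95,
                        riskThresholds = c(0.25, 0.5, 0.75)) {
  baseParams <- computeHLZParams(world@baseline$tmin, world@baseline$tmax,
                                 world@baseline$precip,
                                 reference = world@reference)
  crops <- worldCrops(world)
  foodIds <- names(crops)[vapply(crops, foodFlag, logical(1L))]
  food <- crops[foodIds]
  groups <- vapply(food, cropGroup, character(1L))

  cropland <- totalCroplandMask(crops)
  croplandHa <- totalCroplandArea(crops)

  scs <- lapply(food, delineateSCS, baselineParams = baseParams,
                binning = binning, share = majorShare)

  baselineConsensus <- lapply(scs, function(s) {
    m <- scsMembership(baseParams, s)
    m[!cropland] <- NA
    m
  })

  levels <- names(world@futures)
  futureParams <- lapply(world@futures, function(byGcm)
    lapply(byGcm, function(clim)
      computeHLZParams(clim$tmin, clim$tmax, clim$precip,
                       reference = world@reference)))

  membership <- lapply(levels, function(lv)
    projectMembership(scs, futureParams[[lv]], cropland, as.numeric(lv)))
  names(membership) <- levels

  # --- indicator 1: lowest warming level crossing the risk thresholds
  shares <- lapply(membership, function(cube)
    cellShareOutside(food, cube@consensus))
  riskMaps <- lapply(riskThresholds, function(th)
    lowestRiskLevel(shares, th))
  names(riskMaps) <- as.character(riskThresholds)
  regions <- .regionMaskList(world)
  regionalRisk <- regionalRiskAreaShare(riskMaps[[1L]], regions, croplandHa,
                                        levels = as.numeric(levels))

  # --- indicator 2: production outside the SCS per crop, group, level
  productionOutside <- list()
  groupShares <- list()
  for (lv in levels) {
    stats <- do.call(rbind, lapply(foodIds, function(id) {
      st <- productionOutsideByCrop(food[[id]],
                                    cubeMembers(membership[[lv]], id))
      data.frame(crop = id, level = as.numeric(lv), median = st$median,
                 p25 = st$p25, p75 = st$p75, reference = st$reference)
    }))
    productionOutside[[lv]] <- stats
    groupShares[[lv]] <- aggregateGroupShares(stats, groups)
  }

  # --- cropland-area change within the SCS (per crop, per member, per level)
  areaChanges <- list()
  for (lv in levels) {
    cube <- membership[[lv]]
    areaChanges[[lv]] <- do.call(rbind, lapply(foodIds, function(id) {
      mem <- cubeMembers(cube, id)
      do.call(rbind, lapply(seq_len(dim(mem)[3L]), function(g) {
        gl <- gainLossRatios(baselineConsensus[[id]], mem[, , g], croplandHa)
        data.frame(crop = id, gcm = g, level = as.numeric(lv),
                   aBaseline = gl$aBaseline, aGain = gl$aGain,
                   aLoss = gl$aLoss, aWarming = gl$aWarming,
                   gainPct = gl$gainPct, lossPct = gl$lossPct,
                   netPct = gl$netPct)
      }))
    }))
  }
  cropNet <- do.call(rbind, lapply(levels, function(lv) {
    df <- areaChanges[[lv]]
    do.call(rbind, lapply(split(df, df$crop), function(dc) {
      q <- ensembleQuantiles(dc$netPct)
      data.frame(crop = dc$crop[1L], level = dc$level[1L],
                 netMedian = q$median, netP25 = q$p25, netP75 = q$p75)
    }))
  }))
  rownames(cropNet) <- NULL
  groupArea <- lapply(areaChanges, groupAreaStats, groups = groups)

  # --- potential crop diversity
  baseCount <- potentialDiversity(baselineConsensus, cropland)
  diversity <- list(baseCount = baseCount, levels = list())
  for (lv in levels) {
    cnt <- potentialDiversity(membership[[lv]]@consensus, cropland)
    cats <- classifyDiversityChange(baseCount, cnt)
    diversity$levels[[lv]] <- list(
      count = cnt, categories = cats,
      regionSummary = zonalCategorySummary(cats, regions, croplandHa),
      elevationSummary = zonalCategorySummary(
        cats, elevationBands(world@elevation), croplandHa))
  }

  list(scs = scs, baselineParams = baseParams, membership = membership,
       baselineConsensus = baselineConsensus, shares = shares,
       riskMaps = riskMaps, regionalRisk = regionalRisk,
       productionOutside = productionOutside, groupShares = groupShares,
       areaChanges = areaChanges, cropNet = cropNet, groupArea = groupArea,
       diversity = diversity, croplandMask = cropland,
       croplandArea = croplandHa,
       provenance = provenanceRecord(world@config, binning))
}

.regionMaskList <- function(world) {
  codes <- sort(unique(as.vector(world@regions)))
  masks <- lapply(codes, function(k) world@regions == k)
  names(masks) <- world@regionNames[codes]
  masks
}
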