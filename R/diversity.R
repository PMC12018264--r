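#' @include projection.R
NULL

#' Cropland area within an SCS
#'
#' Sum of physical cropland hectares over the cells whose climate is within
#' the SCS (membership evaluated on the total-cropland extent).
#'
#' @param member logical matrix (consensus or single-member membership)
#' @param croplandArea numeric matrix of cropland hectares per cell
#' @return hectares
#' @export
croplandAreaWithinSCS <- function(member, croplandArea) {
  m <- member
  m[is.na(m)] <- FALSE
  sum(croplandArea[m])
}

#' Percentage net change in cropland area within an SCS
#'
#' (A_warming - A_baseline) / A_baseline x 100. Undefined (NA) when the
#' baseline area is zero.
#'
#' @param aWarming,aBaseline hectares within the SCS at the warming level
#'   and at baseline
#' @return signed percentage, NA when aBaseline is 0
#' @export
netChangePct <- function(aWarming, aBaseline) {
  if (aBaseline == 0) return(NA_real_)
  (aWarming - aBaseline) / aBaseline * 100
}

#' Gained and lost cropland area within an SCS, as ratios to baseline
#'
#' Gain is the cropland area shifting from outside to within the SCS, loss
#' the area shifting from within to outside, both as percentages of the
#' baseline within-SCS area. The identity gain% - loss% = net change %
#' holds exactly.
#'
#' @param memberBaseline,memberLevel logical membership matrices on the
#'   total-cropland extent
#' @param croplandArea numeric matrix [ha]
#' @return list(gainPct, lossPct, netPct, aBaseline, aWarming, aGain, aLoss)
#' @export
gainLossRatios <- function(memberBaseline, memberLevel, croplandArea) {
  mb <- memberBaseline; mb[is.na(mb)] <- FALSE
  ml <- memberLevel;    ml[is.na(ml)] <- FALSE
  aBase <- sum(croplandArea[mb])
  aGain <- sum(croplandArea[!mb & ml])
  aLoss <- sum(croplandArea[mb & !ml])
  aWarm <- aBase + aGain - aLoss
  if (aBase == 0)
    return(list(gainPct = NA_real_, lossPct = NA_real_, netPct = NA_real_,
                aBaseline = 0, aWarming = aWarm, aGain = aGain, aLoss = aLoss))
  list(gainPct = aGain / aBase * 100, lossPct = aLoss / aBase * 100,
       netPct = (aWarm - aBase) / aBase * 100,
       aBaseline = aBase, aWarming = aWarm, aGain = aGain, aLoss = aLoss)
}

#' Crop-group area-change statistics across the ensemble
#'
#' Sums the baseline/gain/loss area components over the crops of each group
#' per ensemble member, converts to gain/loss/net ratios, and summarizes
#' across members with the ensemble median and 25th/75th percentiles.
#'
#' @param changes data.frame with columns crop, gcm, aBaseline, aGain, aLoss
#' @param groups named character vector mapping crop id to group
#' @return data.frame group x statistic ({gain, loss, net} x {median, p25, p75})
#' @export
groupAreaStats <- function(changes, groups) {
  miss <- setdiff(unique(changes$crop), names(groups))
  if (length(miss))
    stop("crops without a group: ", paste(miss, collapse = ", "))
  changes$group <- unname(groups[changes$crop])
  out <- lapply(split(changes, changes$group), function(df) {
    per <- lapply(split(df, df$gcm), function(dg) {
      aB <- sum(dg$aBaseline); aG <- sum(dg$aGain); aL <- sum(dg$aLoss)
      c(gain = aG / aB * 100, loss = aL / aB * 100,
        net = (aG - aL) / aB * 100)
    })
    per <- do.call(rbind, per)
    qs <- lapply(c(gain = "gain", loss = "loss", net = "net"), function(s)
      ensembleQuantiles(per[, s]))
    data.frame(group = df$group[1L],
               gainMedian = qs$gain$median, gainP25 = qs$gain$p25, gainP75 = qs$gain$p75,
               lossMedian = qs$loss$median, lossP25 = qs$loss$p25, lossP75 = qs$loss$p75,
               netMedian = qs$net$median, netP25 = qs$net$p25, netP75 = qs$net$p75)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Potential crop diversity count field
#'
#' Number of crops whose SCS contains each cell's climate, on the
#' total-cropland extent (NA off-cropland), irrespective of where the crops
#' are currently grown.
#'
#' @param consensusByCrop named list of consensus membership matrices
#' @param croplandMask logical matrix, the total-cropland extent
#' @return integer matrix of counts in 0..nCrops (NA off-cropland)
#' @export
potentialDiversity <- function(consensusByCrop, croplandMask) {
  d <- dim(croplandMask)
  cnt <- matrix(0L, d[1L], d[2L])
  for (m in consensusByCrop) {
    mm <- m
    mm[is.na(mm)] <- FALSE
    cnt <- cnt + mm
  }
  cnt[!croplandMask] <- NA_integer_
  cnt
}

#' Legend for the potential-diversity change categories
#'
#' Percentage-change bins in 25-point steps, with the complete loss (-100%)
#' and no-change (0) cases pulled out as their own categories; the negative
#' bins are left-open/right-closed, mirrored on the positive side, and the
#' top positive bin is open-ended (> +75%) so the categories stay exhaustive
#' when the baseline count is small. Cells whose baseline climate is outside
#' every crop's SCS (baseline count 0) become "emerging climatic potential"
#' if at least one SCS arrives under warming, else "marginal in baseline and
#' outside SCS under warming level".
#'
#' @return data.frame with columns code, label
#' @export
diversityCategoryLegend <- function() {
  data.frame(
    code = 1:12,
    label = c("-100%", "(-100%, -75%]", "(-75%, -50%]", "(-50%, -25%]",
              "(-25%, 0%)", "no change", "(0%, +25%]", "(+25%, +50%]",
              "(+50%, +75%]", "> +75%",
              "cropland with emerging climatic potential",
              "marginal in baseline and outside SCS under warming level"))
}

#' Classify per-cell change in potential crop diversity
#'
#' Computes the percentage change in the number of possible crops from
#' baseline to a warming level and assigns each total-cropland cell a
#' category code (see [diversityCategoryLegend()]). Categories are mutually
#' exclusive and exhaustive on the cropland extent.
#'
#' @param baseCount,levelCount integer count fields from
#'   [potentialDiversity()] (NA off-cropland)
#' @return integer matrix of category codes (NA off-cropland)
#' @export
classifyDiversityChange <- function(baseCount, levelCount) {
  if (any(baseCount < 0, na.rm = TRUE) || any(levelCount < 0, na.rm = TRUE))
    stop("diversity counts must be non-negative")
  d <- dim(baseCount)
  cat <- matrix(NA_integer_, d[1L], d[2L])
  ok <- !is.na(baseCount) & !is.na(levelCount)
  zeroBase <- ok & baseCount == 0L
  cat[zeroBase & levelCount >= 1L] <- 11L
  cat[zeroBase & levelCount == 0L] <- 12L
  pos <- ok & baseCount > 0L
  pct <- matrix(NA_real_, d[1L], d[2L])
  pct[pos] <- (levelCount[pos] - baseCount[pos]) / baseCount[pos] * 100
  cat[pos & pct == -100] <- 1L
  cat[pos & pct > -100 & pct <= -75] <- 2L
  cat[pos & pct > -75 & pct <= -50] <- 3L
  cat[pos & pct > -50 & pct <= -25] <- 4L
  cat[pos & pct > -25 & pct < 0] <- 5L
  cat[pos & pct == 0] <- 6L
  cat[pos & pct > 0 & pct <= 25] <- 7L
  cat[pos & pct > 25 & pct <= 50] <- 8L
  cat[pos & pct > 50 & pct <= 75] <- 9L
  cat[pos & pct > 75] <- 10L
  cat
}

#' Zonal summary of diversity-change categories
#'
#' Cropland-area share of each category within each zone (regions, latitude
#' bands or elevation bands). Within a zone the shares over cells with a
#' category and positive cropland area sum to 1.
#'
#' @param categories integer category field from [classifyDiversityChange()]
#' @param zones integer matrix of zone codes or named list of
#'   non-overlapping logical masks
#' @param croplandArea numeric matrix [ha]
#' @return data.frame zone x category with cropland-area shares
#' @export
zonalCategorySummary <- function(categories, zones, croplandArea) {
  masks <- .asMaskList(zones, dim(categories))
  legend <- diversityCategoryLegend()
  rows <- list()
  for (zn in names(masks)) {
    m <- masks[[zn]] & !is.na(categories) & croplandArea > 0
    denom <- sum(croplandArea[m])
    for (k in legend$code) {
      rows[[length(rows) + 1L]] <- data.frame(
        zone = zn, code = k, label = legend$label[k],
        areaShare = if (denom > 0)
          sum(croplandArea[m & categories == k]) / denom else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Potential diversity and its change restricted to one crop group
#'
#' Same semantics as [potentialDiversity()] and
#' [classifyDiversityChange()] with the crop set restricted to the group's
#' crops: emerging climatic potential, for example, then means shifting into
#' the SCS of at least one crop in the group. Emerging-potential areas of
#' different groups may overlap.
#'
#' @param baselineConsensus,levelConsensus named lists of consensus
#'   membership matrices for all crops
#' @param groupCrops character vector of the group's crop ids (non-empty)
#' @param croplandMask logical total-cropland extent
#' @return list(baseCount, levelCount, categories)
#' @export
groupDiversity <- function(baselineConsensus, levelConsensus, groupCrops,
                           croplandMask) {
  if (!length(groupCrops)) stop("empty crop group")
  base <- potentialDiversity(baselineConsensus[groupCrops], croplandMask)
  lvl <- potentialDiversity(levelConsensus[groupCrops], croplandMask)
  list(baseCount = base, levelCount = lvl,
       categories = classifyDiversityChange(base, lvl))
}

#' Default elevation bands
#'
#' Breaks at 500, 1500 and 2500 m; the > 2500 m band isolates the high
#' elevation zone where emerging climatic potential concentrates.
#'
#' @param elevation numeric matrix [m]
#' @param breaks ascending interior break elevations [m]
#' @return named list of logical masks, one per band
#' @export
elevationBands <- function(elevation, breaks = c(500, 1500, 2500)) {
  edges <- c(-Inf, breaks, Inf)
  labs <- c(paste0("<", breaks[1L], "m"),
            paste0(head2(breaks), "-", breaks[-1L], "m"),
            paste0(">", breaks[length(breaks)], "m"))
  masks <- lapply(seq_len(length(edges) - 1L), function(i)
    elevation >= edges[i] & elevation < edges[i + 1L])
  names(masks) <- labs
  masks
}

head2 <- function(x) x[-length(x)]
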