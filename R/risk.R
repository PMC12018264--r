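#' @include projection.R
NULL

#' Per-cell share of current production outside the SCSs
#'
#' Production-weighted share of the crops' current production in each cell
#' that falls outside the respective crop-specific SCS, using consensus
#' (majority-vote) membership. Cells with zero total production are NA.
#'
#' @param crops named list of [CropLayer-class]
#' @param consensusByCrop named list of consensus logical matrices (NA or
#'   FALSE = outside)
#' @return numeric matrix of fractions in [0, 1] (NA where no production)
#' @export
cellShareOutside <- function(crops, consensusByCrop) {
  d <- gridDim(crops[[1L]])
  tot <- matrix(0, d[1L], d[2L])
  out <- matrix(0, d[1L], d[2L])
  for (id in names(crops)) {
    p <- production(crops[[id]])
    within <- consensusByCrop[[id]]
    within[is.na(within)] <- FALSE
    tot <- tot + p
    out <- out + p * !within
  }
  share <- out / tot
  share[tot == 0] <- NA
  share
}

#' Lowest warming level pushing a cell's production past a risk threshold
#'
#' Scans warming levels in ascending order and records, per cell, the first
#' level at which the share of production outside the SCSs reaches the
#' threshold. Cells never crossing get Inf ("never": at least 1 - threshold
#' of production stays within under all levels); cells with no production
#' are NA.
#'
#' @param sharesByLevel named list of share fields from [cellShareOutside()],
#'   names = warming levels, ascending
#' @param threshold risk threshold fraction in (0, 1] (e.g. 0.25 for
#'   "considerable risk")
#' @return numeric matrix: warming level, Inf = never, NA = no production
#' @export
lowestRiskLevel <- function(sharesByLevel, threshold = 0.25) {
  stopifnot(length(sharesByLevel) >= 1L, threshold > 0, threshold <= 1)
  levels <- as.numeric(names(sharesByLevel))
  if (anyNA(levels) || is.unsorted(levels, strictly = TRUE))
    stop("sharesByLevel must be named by strictly ascending warming levels")
  d <- dim(sharesByLevel[[1L]])
  risk <- matrix(Inf, d[1L], d[2L])
  for (i in rev(seq_along(levels))) {
    s <- sharesByLevel[[i]]
    if (!identical(dim(s), d)) stop("missing or misaligned level field")
    risk[!is.na(s) & s >= threshold] <- levels[i]
  }
  risk[is.na(sharesByLevel[[1L]])] <- NA
  risk
}

#' Regional share of cropland area at risk per warming level
#'
#' For each region and warming level, the share of the region's cropland
#' hectares whose risk category (from [lowestRiskLevel()]) is at or below
#' the level. Shares are cumulative, hence non-decreasing in level. The
#' denominator is all regional cropland hectares, including cropland cells
#' with no food-crop production.
#'
#' @param risk matrix from [lowestRiskLevel()]
#' @param regions integer matrix of region codes (a partition) or named
#'   list of non-overlapping logical masks
#' @param croplandArea numeric matrix of cropland hectares per cell
#' @param levels warming levels to tabulate (default: levels present)
#' @return data.frame region x level with cropland-area shares
#' @export
regionalRiskAreaShare <- function(risk, regions, croplandArea,
                                  levels = sort(unique(risk[is.finite(risk)]))) {
  masks <- .asMaskList(regions, dim(risk))
  rows <- list()
  for (rn in names(masks)) {
    m <- masks[[rn]] & croplandArea > 0
    denom <- sum(croplandArea[m])
    for (lv in levels) {
      hit <- m & !is.na(risk) & risk <= lv
      rows[[length(rows) + 1L]] <- data.frame(
        region = rn, level = lv,
        areaShare = if (denom > 0) sum(croplandArea[hit]) / denom else NA_real_)
    }
  }
  do.call(rbind, rows)
}

.asMaskList <- function(regions, d) {
  if (is.list(regions)) {
    overlap <- Reduce(`+`, lapply(regions, function(m) m + 0))
    if (any(overlap > 1)) stop("region masks overlap")
    return(regions)
  }
  stopifnot(identical(dim(regions), d))
  codes <- sort(unique(as.vector(regions[!is.na(regions)])))
  nms <- names(attr(regions, "regionNames"))
  masks <- lapply(codes, function(k) !is.na(regions) & regions == k)
  names(masks) <- as.character(codes)
  masks
}

#' Share of a crop's production outside its SCS, with ensemble spread
#'
#' Per ensemble member, the crop production summed over cells estimated
#' outside the SCS, divided by the reference total; then the ensemble
#' median and 25th/75th percentiles. Production and membership can first be
#' restricted to a region mask for regional aggregation.
#'
#' @param crop a [CropLayer-class]
#' @param members logical rows x cols x nGcm membership array (NA = outside
#'   extent, counted outside)
#' @param regionMask optional logical matrix restricting the aggregation
#' @return list(median, p25, p75, perGcm, reference) — shares as fractions,
#'   reference in tons
#' @export
productionOutsideByCrop <- function(crop, members, regionMask = NULL) {
  p <- production(crop)
  if (!is.null(regionMask)) p <- p * (regionMask + 0)
  total <- sum(p)
  if (total <= 0) stop("zero reference production for crop '", cropId(crop), "'")
  n <- dim(members)[3L]
  per <- vapply(seq_len(n), function(g) {
    within <- members[, , g]
    within[is.na(within)] <- FALSE
    sum(p[!within]) / total
  }, numeric(1L))
  q <- ensembleQuantiles(per)
  c(q, list(perGcm = per, reference = total))
}

#' Aggregate production-outside statistics into crop groups
#'
#' Group medians/percentiles are the sums of the member crops' statistics in
#' tons divided by the summed reference production, and likewise for all
#' crops in total.
#'
#' @param stats data.frame with columns crop, median, p25, p75 (shares) and
#'   reference (tons)
#' @param groups named character vector mapping crop id to group
#' @return data.frame group x {median, p25, p75} shares, including "all"
#' @export
aggregateGroupShares <- function(stats, groups) {
  miss <- setdiff(stats$crop, names(groups))
  if (length(miss))
    stop("crops without a group: ", paste(miss, collapse = ", "))
  stats$group <- unname(groups[stats$crop])
  agg <- function(df, label) {
    ref <- sum(df$reference)
    data.frame(group = label,
               median = sum(df$median * df$reference) / ref,
               p25 = sum(df$p25 * df$reference) / ref,
               p75 = sum(df$p75 * df$reference) / ref,
               reference = ref)
  }
  out <- do.call(rbind, lapply(split(stats, stats$group), function(df)
    agg(df, df$group[1L])))
  out <- rbind(out, agg(stats, "all"))
  rownames(out) <- NULL
  out
}
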