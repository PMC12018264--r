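#' @include scs.R
NULL

#' Per-ensemble-member SCS membership on an extent
#'
#' Evaluates one crop's SCS membership for each ensemble member's climate
#' parameters, masked to the analysis extent: cells off the extent are NA
#' and never appear in any aggregate.
#'
#' @param scs an [SCSDefinition-class]
#' @param paramsByGcm list of [HLZParamSet-class], one per ensemble member
#' @param extent logical matrix, the analysis extent
#' @return logical rows x cols x nGcm array (NA off-extent)
#' @export
ensembleMembership <- function(scs, paramsByGcm, extent) {
  stopifnot(length(paramsByGcm) >= 1L)
  d <- dim(extent)
  for (p in paramsByGcm)
    if (!identical(gridDim(p), d))
      stop("ensemble member grids disagree with the extent grid")
  arr <- array(NA, c(d, length(paramsByGcm)))
  for (g in seq_along(paramsByGcm)) {
    m <- scsMembership(paramsByGcm[[g]], scs)
    m[!extent] <- NA
    arr[, , g] <- m
  }
  arr
}

#' Majority vote over ensemble members
#'
#' A cell is within by consensus iff at least ceil(n/2) of the n member
#' fields say within ("at least half", inclusive: 4 of 8 suffices). Cells
#' that are NA in the members (off-extent) stay NA.
#'
#' @param members logical rows x cols x n array (or a matrix for n = 1)
#' @return logical matrix
#' @export
majorityVote <- function(members) {
  if (is.matrix(members)) members <- array(members, c(dim(members), 1L))
  d <- dim(members)
  n <- d[3L]
  flat <- matrix(members, d[1L] * d[2L], n)
  cnt <- rowSums(flat, na.rm = TRUE)
  cons <- cnt >= ceiling(n / 2)
  cons[rowSums(!is.na(flat)) == 0L] <- NA
  matrix(cons, d[1L], d[2L])
}

#' Ensemble summary quantiles
#'
#' Median and 25th/75th percentiles of per-member scalar estimates, using
#' linear interpolation between order statistics (quantile type 7; recorded
#' in output metadata).
#'
#' @param values numeric vector, one value per ensemble member
#' @return list(median, p25, p75)
#' @export
ensembleQuantiles <- function(values) {
  if (!length(values)) stop("empty ensemble value list")
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  list(median = q[1L], p25 = q[2L], p75 = q[3L])
}

#' Build a MembershipCube for a set of crops at one warming level
#'
#' Evaluates per-crop, per-member membership on the extent and forms the
#' majority-vote consensus per crop.
#'
#' @param scsList named list of [SCSDefinition-class] (names = crop ids)
#' @param paramsByGcm list of [HLZParamSet-class], one per ensemble member
#' @param extent logical matrix
#' @param level warming-level label [deg C]
#' @return a [MembershipCube-class]
#' @export
projectMembership <- function(scsList, paramsByGcm, extent, level) {
  members <- lapply(scsList, ensembleMembership, paramsByGcm = paramsByGcm,
                    extent = extent)
  consensus <- lapply(members, majorityVote)
  new("MembershipCube", level = level, members = members,
      consensus = consensus, extent = extent)
}
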