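#' @include binning.R climate.R
NULL

#' Select a crop's major-production cells
#'
#' Cells are ranked by production descending (ties broken by row-major cell
#' order) and the smallest prefix whose cumulative production reaches
#' `share` of the crop total is returned; the cell that crosses the
#' threshold is included, so the realized captured share is >= the nominal
#' share.
#'
#' @param crop a [CropLayer-class]
#' @param share cumulative production fraction defining "major" (default
#'   0.95, the highest 95 percent of production)
#' @return integer vector of cell indices (column-major into the grid)
#' @export
selectMajorCells <- function(crop, share = 0.95) {
  stopifnot(share > 0, share <= 1)
  p <- as.vector(production(crop))
  total <- sum(p)
  if (total <= 0) stop("crop '", cropId(crop), "' has zero total production")
  ord <- order(-p, seq_along(p))
  pos <- ord[p[ord] > 0]
  cum <- cumsum(p[pos])
  k <- which(cum >= share * total - 1e-9 * total)[1L]
  pos[seq_len(k)]
}

#' Select a crop's marginal-production cells
#'
#' The complement of the major-production cells within the crop's
#' positive-production cells: the last-ranked cells contributing the lowest
#' `share` of the crop's global total. When a total-cropland mask is given,
#' zero-production cropland cells are included too ("marginal or no
#' production").
#'
#' @param crop a [CropLayer-class]
#' @param share marginal fraction of total production (default 0.05)
#' @param croplandMask optional logical matrix; include zero-production
#'   cropland cells from this mask
#' @return integer vector of cell indices
#' @export
selectMarginalCells <- function(crop, share = 0.05, croplandMask = NULL) {
  p <- as.vector(production(crop))
  major <- selectMajorCells(crop, 1 - share)
  marginal <- setdiff(which(p > 0), major)
  if (!is.null(croplandMask))
    marginal <- sort(union(marginal, which(as.vector(croplandMask) & p == 0)))
  marginal
}

#' Delineate a crop's Safe Climatic Space
#'
#' Maps each major-production cell of the crop onto the discretized
#' (precipitation, biotemperature, aridity, frost) climate space under
#' baseline climate; the SCS is the set of bins occupied by at least one
#' such cell. Major cells with non-finite parameters are excluded and
#' counted in the provenance.
#'
#' @param crop a [CropLayer-class]
#' @param baselineParams baseline [HLZParamSet-class] on the crop's grid
#' @param binning a [ClimateBinning-class]
#' @param share major-production share (default 0.95)
#' @return an [SCSDefinition-class]
#' @export
delineateSCS <- function(crop, baselineParams, binning = climateBinning(),
                         share = 0.95) {
  if (!identical(gridDim(crop), gridDim(baselineParams)))
    stop("crop and baseline parameter grids are misaligned")
  cells <- selectMajorCells(crop, share)
  keys <- binKey(baselineParams, binning)[cells]
  dropped <- sum(is.na(keys))
  keys <- keys[!is.na(keys)]
  if (!length(keys))
    stop("no major cell of crop '", cropId(crop), "' has finite climate parameters")
  p <- as.vector(production(crop))
  captured <- sum(p[cells][!is.na(binKey(baselineParams, binning)[cells])]) / sum(p)
  new("SCSDefinition", cropId = cropId(crop), binning = binning,
      occupied = sort(unique(keys)),
      provenance = list(nominalShare = share,
                        capturedShare = captured,
                        nCells = length(cells),
                        nDroppedNonFinite = dropped,
                        binsPerClass = binning@binsPerClass))
}

#' Test membership of climates in a Safe Climatic Space
#'
#' A cell is within the SCS iff its (precipitation, biotemperature, aridity,
#' frost) bin 4-tuple is one of the occupied bins. Cells with non-finite
#' parameters are outside.
#'
#' @param params an [HLZParamSet-class] on any grid (same units)
#' @param scs an [SCSDefinition-class]
#' @return logical matrix, TRUE = within
#' @export
scsMembership <- function(params, scs) {
  keys <- binKey(params, scs@binning)
  m <- keys %in% scs@occupied
  matrix(m, nrow(params@annualPrecip), ncol(params@annualPrecip))
}
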