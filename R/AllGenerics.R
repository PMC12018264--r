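#' @include AllClasses.R
NULL

#' Grid dimension of a gridded object
#' @param x a gridded cropSCS object
#' @return integer c(rows, cols)
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridDim
#' @export
setMethod("gridDim", "MonthlyClimatology", function(x) dim(x@values)[1:2])

#' @rdname gridDim
#' @export
setMethod("gridDim", "HLZParamSet", function(x) dim(x@annualPrecip))

#' @rdname gridDim
#' @export
setMethod("gridDim", "CropLayer", function(x) dim(x@production))

#' @rdname gridDim
#' @export
setMethod("gridDim", "SyntheticWorld",
          function(x) gridDim(x@baseline$precip))

#' Accessors for MonthlyClimatology
#' @param x a `MonthlyClimatology`
#' @return `climVariable` the variable name; `climValues` the
#'   rows x cols x 12 array
#' @export
climVariable <- function(x) x@variable

#' @rdname climVariable
#' @export
climValues <- function(x) x@values

#' Accessors for HLZParamSet
#'
#' Matrix-valued accessors for the five Holdridge parameters.
#' @param x an `HLZParamSet`
#' @return a numeric (or logical, for `frostFree`) matrix
#' @export
annualPrecip <- function(x) x@annualPrecip

#' @rdname annualPrecip
#' @export
biotemp <- function(x) x@biotemperature

#' @rdname annualPrecip
#' @export
pet <- function(x) x@pet

#' @rdname annualPrecip
#' @export
aridity <- function(x) x@aridity

#' @rdname annualPrecip
#' @export
frostFree <- function(x) x@frostFree

#' Accessors for CropLayer
#' @param x a `CropLayer`
#' @return production or physical-area matrix, crop id, food flag, group
#' @export
production <- function(x) x@production

#' @rdname production
#' @export
physicalArea <- function(x) x@physicalArea

#' @rdname production
#' @export
cropId <- function(x) x@cropId

#' @rdname production
#' @export
foodFlag <- function(x) x@foodFlag

#' @rdname production
#' @export
cropGroup <- function(x) x@group

#' Accessors for SCSDefinition
#' @param x an `SCSDefinition`
#' @return occupied bin keys, the binning, or the provenance list
#' @export
occupiedBins <- function(x) x@occupied

#' @rdname occupiedBins
#' @export
scsBinning <- function(x) x@binning

#' @rdname occupiedBins
#' @export
scsProvenance <- function(x) x@provenance

#' Accessors for MembershipCube
#' @param x a `MembershipCube`
#' @param crop crop id
#' @return member array, consensus matrix, extent mask or level
#' @export
cubeMembers <- function(x, crop) x@members[[crop]]

#' @rdname cubeMembers
#' @export
cubeConsensus <- function(x, crop) x@consensus[[crop]]

#' @rdname cubeMembers
#' @export
cubeExtent <- function(x) x@extent

#' @rdname cubeMembers
#' @export
cubeLevel <- function(x) x@level

#' Accessors for SyntheticWorld
#' @param x a `SyntheticWorld`
#' @return the requested component
#' @export
worldBaseline <- function(x) x@baseline

#' @rdname worldBaseline
#' @export
worldReference <- function(x) x@reference

#' @rdname worldBaseline
#' @export
worldFutures <- function(x) x@futures

#' @rdname worldBaseline
#' @export
worldCrops <- function(x) x@crops

#' @rdname worldBaseline
#' @export
worldRegions <- function(x) x@regions

#' @rdname worldBaseline
#' @export
worldRegionNames <- function(x) x@regionNames

#' @rdname worldBaseline
#' @export
worldElevation <- function(x) x@elevation

#' @rdname worldBaseline
#' @export
trueNiches <- function(x) x@niches

#' @rdname worldBaseline
#' @export
worldSeed <- function(x) x@config$seed

setMethod("show", "MonthlyClimatology", function(object) {
  d <- dim(object@values)
  cat(sprintf("MonthlyClimatology '%s' on a %d x %d grid (12 months)\n",
              object@variable, d[1], d[2]))
  cat(sprintf("  range: [%.3g, %.3g]\n",
              suppressWarnings(min(object@values, na.rm = TRUE)),
              suppressWarnings(max(object@values, na.rm = TRUE))))
})

setMethod("show", "HLZParamSet", function(object) {
  d <- dim(object@annualPrecip)
  cat(sprintf("HLZParamSet on a %d x %d grid\n", d[1], d[2]))
  cat(sprintf("  biotemperature: [%.2f, %.2f] degC; annual precip: [%.0f, %.0f] mm\n",
              min(object@biotemperature, na.rm = TRUE),
              max(object@biotemperature, na.rm = TRUE),
              min(object@annualPrecip, na.rm = TRUE),
              max(object@annualPrecip, na.rm = TRUE)))
  cat(sprintf("  frost-free cells: %d; aridity cap: %g\n",
              sum(object@frostFree, na.rm = TRUE), object@aridityCap))
})

setMethod("show", "SCSDefinition", function(object) {
  cat(sprintf("SCSDefinition for crop '%s': %d occupied climate bins\n",
              object@cropId, length(object@occupied)))
  pv <- object@provenance
  if (!is.null(pv$capturedShare))
    cat(sprintf("  captured production share: %.4f (%d major cells, binsPerClass = %g)\n",
                pv$capturedShare, pv$nCells, object@binning@binsPerClass))
})

setMethod("show", "CropLayer", function(object) {
  cat(sprintf("CropLayer '%s'%s: total production %.4g t on %d cells, %.4g ha\n",
              object@cropId,
              if (isTRUE(object@foodFlag)) sprintf(" [food: %s]", object@group) else "",
              sum(object@production), sum(object@production > 0),
              sum(object@physicalArea)))
})

setMethod("show", "MembershipCube", function(object) {
  n <- if (length(object@members)) dim(object@members[[1]])[3] else 0L
  cat(sprintf("MembershipCube at %.1f degC: %d crops x %d ensemble members\n",
              object@level, length(object@members), n))
})

setMethod("show", "SyntheticWorld", function(object) {
  d <- gridDim(object)
  cat(sprintf("SyntheticWorld %d x %d: %d crops, %d GCMs, %d warming levels (seed %d)\n",
              d[1], d[2], length(object@crops),
              object@config$nGcms, length(object@config$warmingDeltas),
              object@config$seed))
})
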