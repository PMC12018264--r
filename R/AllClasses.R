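#' @import methods
NULL

#' MonthlyClimatology: twelve monthly gridded fields of one climate variable
#'
#' The raw material of every Holdridge parameter. Values are stored as a
#' rows x cols x 12 array; months run January..December. Temperature is in
#' degrees Celsius, precipitation in mm/month.
#'
#' @slot variable one of "tmin", "tmax", "tmean", "precip"
#' @slot values numeric array with dim c(rows, cols, 12)
#' @exportClass MonthlyClimatology
setClass("MonthlyClimatology",
  slots = c(variable = "character", values = "array"))

setValidity("MonthlyClimatology", function(object) {
  msg <- character()
  if (length(object@variable) != 1L ||
      !object@variable %in% c("tmin", "tmax", "tmean", "precip"))
    msg <- c(msg, "variable must be one of tmin, tmax, tmean, precip")
  d <- dim(object@values)
  if (length(d) != 3L || d[3L] != 12L)
    msg <- c(msg, "values must be a rows x cols x 12 array (exactly 12 months)")
  if (length(object@values) && object@variable == "precip" &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "monthly precipitation must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a MonthlyClimatology
#'
#' @param variable "tmin", "tmax", "tmean" or "precip"
#' @param values rows x cols x 12 array, or a single rows x cols matrix
#'   replicated to all 12 months, or a length-12 vector giving one value per
#'   month on a grid of dimension `dim`
#' @param dim optional c(rows, cols) used when `values` is a length-12 vector
#' @return a `MonthlyClimatology`
#' @export
MonthlyClimatology <- function(variable, values, dim = NULL) {
  if (is.matrix(values)) {
    values <- array(rep(values, 12L), c(base::dim(values), 12L))
  } else if (is.vector(values) && length(values) == 12L) {
    if (is.null(dim)) stop("`dim` is required when `values` is a monthly vector")
    values <- array(rep(values, each = prod(dim)), c(dim, 12L))
  }
  new("MonthlyClimatology", variable = variable, values = values)
}

#' HLZParamSet: Holdridge life-zone parameters on a grid
#'
#' Per-cell annual precipitation [mm/yr], biotemperature [deg C], potential
#' evapotranspiration [mm/yr], aridity (PET / precipitation, dimensionless)
#' and the annual frost indicator (TRUE where no month has sub-zero minimum
#' temperature). `aridityCap` records the finite value substituted where
#' precipitation is zero but PET is positive.
#'
#' @slot annualPrecip numeric matrix [mm/yr]
#' @slot biotemperature numeric matrix [deg C]
#' @slot pet numeric matrix [mm/yr]
#' @slot aridity numeric matrix
#' @slot frostFree logical matrix
#' @slot aridityCap numeric scalar
#' @exportClass HLZParamSet
setClass("HLZParamSet",
  slots = c(annualPrecip = "matrix", biotemperature = "matrix",
            pet = "matrix", aridity = "matrix", frostFree = "matrix",
            aridityCap = "numeric"))

setValidity("HLZParamSet", function(object) {
  msg <- character()
  d <- dim(object@annualPrecip)
  for (s in c("biotemperature", "pet", "aridity", "frostFree"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("slot '%s' is not on the same grid as annualPrecip", s))
  if (any(object@annualPrecip < 0, na.rm = TRUE))
    msg <- c(msg, "annualPrecip must be >= 0")
  if (any(object@biotemperature < 0, na.rm = TRUE))
    msg <- c(msg, "biotemperature must be >= 0")
  ok <- is.finite(object@pet) & is.finite(object@biotemperature)
  if (any(abs(object@pet[ok] - 58.93 * object@biotemperature[ok]) >
          1e-6 * pmax(1, object@pet[ok])))
    msg <- c(msg, "pet must equal 58.93 x biotemperature")
  if (length(msg)) msg else TRUE
})

#' ClimateBinning: discretization of the Holdridge parameter space
#'
#' Strictly increasing interior bin edges per axis; values below the first
#' edge or at/above the last fall into open-ended outer bins, so every finite
#' value maps to exactly one bin. Intervals are half-open [low, high). The
#' frost indicator is a fourth, boolean axis.
#'
#' @slot precipEdges numeric, edges for annual precipitation [mm/yr]
#' @slot biotempEdges numeric, edges for biotemperature [deg C]
#' @slot aridityEdges numeric, edges for aridity
#' @slot binsPerClass numeric, sub-bins per Holdridge class used to build the
#'   default edges (provenance only)
#' @exportClass ClimateBinning
setClass("ClimateBinning",
  slots = c(precipEdges = "numeric", biotempEdges = "numeric",
            aridityEdges = "numeric", binsPerClass = "numeric"))

setValidity("ClimateBinning", function(object) {
  msg <- character()
  for (s in c("precipEdges", "biotempEdges", "aridityEdges")) {
    e <- slot(object, s)
    if (length(e) < 1L) msg <- c(msg, sprintf("%s needs at least one edge", s))
    if (any(diff(e) <= 0)) msg <- c(msg, sprintf("%s must be strictly increasing", s))
    if (any(!is.finite(e))) msg <- c(msg, sprintf("%s must be finite", s))
  }
  if (length(msg)) msg else TRUE
})

#' SCSDefinition: a crop's Safe Climatic Space as a set of occupied bins
#'
#' The climatic niche of a crop: the set of (precipitation, biotemperature,
#' aridity, frost) bins occupied by at least one of its major-production
#' cells under baseline climate. `occupied` holds bin keys formed by
#' [binKey()]; `provenance` records the realized captured production share,
#' the number of cells used, cells dropped for non-finite parameters, and the
#' binning resolution.
#'
#' @slot cropId character
#' @slot binning a `ClimateBinning`
#' @slot occupied character vector of occupied bin keys
#' @slot provenance list
#' @exportClass SCSDefinition
setClass("SCSDefinition",
  slots = c(cropId = "character", binning = "ClimateBinning",
            occupied = "character", provenance = "list"))

setValidity("SCSDefinition", function(object) {
  if (length(object@occupied) < 1L)
    return("occupied bin set must be non-empty")
  if (anyDuplicated(object@occupied))
    return("occupied bin keys must be unique")
  TRUE
})

#' CropLayer: one crop's production and physical area rasters plus metadata
#'
#' @slot cropId character
#' @slot production numeric matrix [metric tons/cell]
#' @slot physicalArea numeric matrix [ha/cell]
#' @slot foodFlag logical, is this a food crop
#' @slot group character, crop group (one of the five food-crop groups for
#'   food crops)
#' @exportClass CropLayer
setClass("CropLayer",
  slots = c(cropId = "character", production = "matrix",
            physicalArea = "matrix", foodFlag = "logical", group = "character"))

setValidity("CropLayer", function(object) {
  msg <- character()
  if (!identical(dim(object@production), dim(object@physicalArea)))
    msg <- c(msg, "production and physicalArea must share one grid")
  if (any(object@production < 0, na.rm = TRUE))
    msg <- c(msg, "production must be >= 0")
  if (any(object@physicalArea < 0, na.rm = TRUE))
    msg <- c(msg, "physicalArea must be >= 0")
  if (isTRUE(object@foodFlag) && (is.na(object@group) || !nzchar(object@group)))
    msg <- c(msg, "every food crop must have a crop group")
  if (length(msg)) msg else TRUE
})

#' MembershipCube: per-crop, per-GCM SCS membership at one warming level
#'
#' Boolean within-SCS fields for each crop and ensemble member, with the
#' majority-vote consensus field per crop. Cells off the analysis extent are
#' NA and never enter any aggregate.
#'
#' @slot level numeric warming-level label [deg C]
#' @slot members named list; per crop a rows x cols x nGcm logical array
#' @slot consensus named list; per crop a rows x cols logical matrix
#' @slot extent logical matrix, the analysis extent mask
#' @exportClass MembershipCube
setClass("MembershipCube",
  slots = c(level = "numeric", members = "list", consensus = "list",
            extent = "matrix"))

setValidity("MembershipCube", function(object) {
  msg <- character()
  if (!identical(sort(names(object@members)), sort(names(object@consensus))))
    msg <- c(msg, "members and consensus must cover the same crops")
  for (cr in names(object@members)) {
    m <- object@members[[cr]]
    n <- dim(m)[3L]
    cons <- majorityVote(m)
    if (!identical(cons, object@consensus[[cr]]))
      msg <- c(msg, sprintf(
        "consensus for crop '%s' is not the >= ceil(n/2) member vote", cr))
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a small self-consistent world with known ground truth
#'
#' Bundle produced by [generateWorld()]: baseline and reference monthly
#' climatologies, per-GCM per-level future climatologies, crop layers whose
#' production was generated from known true niches, region masks, an
#' elevation field, and the true-niche table itself.
#'
#' @slot config list, the validated [worldConfig()]
#' @slot baseline list of MonthlyClimatology (tmin, tmax, precip)
#' @slot reference list of MonthlyClimatology (tmean, tmin, tmax) for bias
#'   correction (zero-bias by construction)
#' @slot futures nested list: futures[[level]][[gcm]] = list(tmin, tmax, precip)
#' @slot crops named list of CropLayer
#' @slot regions integer matrix of region codes
#' @slot regionNames character, names for the region codes
#' @slot elevation numeric matrix [m]
#' @slot niches data.frame of true niche bounds per crop
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  slots = c(config = "list", baseline = "list", reference = "list",
            futures = "list", crops = "list", regions = "matrix",
            regionNames = "character", elevation = "matrix",
            niches = "data.frame"))
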