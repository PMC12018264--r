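#' @include AllClasses.R
NULL

HOLDRIDGE_PET_CONSTANT <- 58.93

.checkAligned <- function(...) {
  objs <- list(...)
  d <- gridDim(objs[[1]])
  for (o in objs[-1])
    if (!identical(gridDim(o), d))
      stop("grids are misaligned: expected ", paste(d, collapse = " x "),
           ", got ", paste(gridDim(o), collapse = " x "))
  invisible(d)
}

.monthSum <- function(clim) {
  d <- dim(clim@values)
  matrix(rowSums(matrix(clim@values, d[1] * d[2], 12L)), d[1], d[2])
}

#' Estimate monthly mean temperature from monthly minima and maxima
#'
#' Monthly mean temperature is taken as the midpoint of the monthly minimum
#' and maximum temperatures, cell-wise and month-wise.
#'
#' @param tmin,tmax `MonthlyClimatology` objects for the same grid
#' @return a `MonthlyClimatology` with variable "tmean"
#' @export
monthlyMeanEstimate <- function(tmin, tmax) {
  stopifnot(climVariable(tmin) == "tmin", climVariable(tmax) == "tmax")
  .checkAligned(tmin, tmax)
  new("MonthlyClimatology", variable = "tmean",
      values = (tmin@values + tmax@values) / 2)
}

#' Bias-correct an estimated monthly mean temperature
#'
#' Adds, per cell and month, the offset between a reference period's true
#' monthly mean and the midpoint of its monthly minima and maxima. With a
#' zero-bias reference the input is returned unchanged. The correction is
#' additive and deliberately not idempotent: applying it twice adds the bias
#' twice.
#'
#' @param tmeanEst estimated monthly mean (`MonthlyClimatology`, "tmean")
#' @param refTmean,refTmin,refTmax reference-period climatologies
#' @return bias-corrected `MonthlyClimatology` ("tmean")
#' @export
biasCorrectTmean <- function(tmeanEst, refTmean, refTmin, refTmax) {
  stopifnot(climVariable(tmeanEst) == "tmean", climVariable(refTmean) == "tmean",
            climVariable(refTmin) == "tmin", climVariable(refTmax) == "tmax")
  .checkAligned(tmeanEst, refTmean, refTmin, refTmax)
  if (anyNA(refTmean@values) || anyNA(refTmin@values) || anyNA(refTmax@values))
    stop("reference climatology has missing months/cells")
  bias <- refTmean@values - (refTmin@values + refTmax@values) / 2
  new("MonthlyClimatology", variable = "tmean",
      values = tmeanEst@values + bias)
}

#' Annual precipitation
#'
#' Cell-wise sum of the twelve monthly precipitation fields [mm/yr].
#'
#' @param precip `MonthlyClimatology` with variable "precip"
#' @return numeric matrix [mm/yr]
#' @export
annualPrecipitation <- function(precip) {
  stopifnot(climVariable(precip) == "precip")
  if (any(precip@values < 0, na.rm = TRUE))
    stop("negative monthly precipitation")
  .monthSum(precip)
}

#' Annual biotemperature
#'
#' Monthly mean temperatures are clamped below at 0 degC, summed over the
#' twelve months and divided by 12 (the Holdridge annualization; see the
#' methods vignette for why the denominator is 12 and not the count of
#' positive months). An optional upper clamp per month is available for
#' Holdridge variants that cap biotemperature; default is no cap.
#'
#' @param tmean `MonthlyClimatology` with variable "tmean"
#' @param biotempCap optional per-month upper clamp [deg C]; `Inf` disables
#' @return numeric matrix [deg C]
#' @export
biotemperature <- function(tmean, biotempCap = Inf) {
  stopifnot(climVariable(tmean) == "tmean")
  v <- pmin(pmax(tmean@values, 0), biotempCap)
  d <- dim(v)
  matrix(rowSums(matrix(v, d[1] * d[2], 12L)) / 12, d[1], d[2])
}

#' Annual potential evapotranspiration (Holdridge)
#'
#' Monthly biotemperature times the Holdridge constant 58.93, summed over
#' months and annualized; equivalently 58.93 x annual biotemperature [mm/yr].
#'
#' @inheritParams biotemperature
#' @return numeric matrix [mm/yr]
#' @export
annualPET <- function(tmean, biotempCap = Inf) {
  HOLDRIDGE_PET_CONSTANT * biotemperature(tmean, biotempCap)
}

#' Aridity index
#'
#' Annual PET divided by annual precipitation. Where precipitation is zero
#' but PET is positive the ratio is capped at `cap` (beyond the driest
#' Holdridge humidity-province edge) to keep binning finite; where both are
#' zero the aridity is 0.
#'
#' @param pet numeric matrix [mm/yr]
#' @param annualPrecip numeric matrix [mm/yr]
#' @param cap finite substitute for division by zero precipitation
#' @return numeric matrix
#' @export
aridityIndex <- function(pet, annualPrecip, cap = 2^8) {
  if (any(pet < 0, na.rm = TRUE) || any(annualPrecip < 0, na.rm = TRUE))
    stop("pet and annualPrecip must be non-negative")
  .checkDimEq(pet, annualPrecip)
  a <- pet / annualPrecip
  a[annualPrecip == 0 & pet > 0] <- cap
  a[annualPrecip == 0 & pet == 0] <- 0
  a
}

.checkDimEq <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("fields are misaligned")
  invisible(dim(x))
}

#' Annual frost indicator
#'
#' TRUE where no month's minimum temperature is at or below 0 degC (strictly
#' positive minima in all twelve months); used to separate temperate from
#' subtropical Holdridge zones.
#'
#' @param tmin `MonthlyClimatology` with variable "tmin"
#' @return logical matrix
#' @export
frostIndicator <- function(tmin) {
  stopifnot(climVariable(tmin) == "tmin")
  d <- dim(tmin@values)
  m <- matrix(tmin@values, d[1] * d[2], 12L)
  matrix(apply(m, 1L, min) > 0, d[1], d[2])
}

#' Warming-level specification
#'
#' One row of the warming-level table: the warming level is represented by
#' climate linearly interpolated between two period climatologies whose
#' centre years x0 < x1 bracket the IPCC central-estimate crossing year x.
#'
#' @param level warming level label [deg C]
#' @param ssp scenario name
#' @param x IPCC central-estimate centre year
#' @param x0,x1 centre years of the earlier/later period climatologies
#' @return a validated list
#' @export
warmingLevelSpec <- function(level, ssp, x, x0, x1) {
  stopifnot(is.finite(level), is.finite(x), is.finite(x0), is.finite(x1))
  if (x0 >= x1) stop("x0 must be earlier than x1")
  if (x < x0 || x > x1) stop("x must lie within [x0, x1]")
  list(level = level, ssp = as.character(ssp), x = x, x0 = x0, x1 = x1)
}

#' Interpolate climate data to a warming-level crossing year
#'
#' Cell-wise linear interpolation between the earlier (Y0) and later (Y1)
#' period data with weights (x1 - x)/(x1 - x0) and (x - x0)/(x1 - x0).
#' Works on numeric fields/arrays, `MonthlyClimatology` objects and whole
#' `HLZParamSet` bundles; for the latter the binary frost indicator is
#' interpolated numerically and re-thresholded at >= 0.5.
#'
#' @param Y0,Y1 fields of the same kind on one grid
#' @param spec a [warmingLevelSpec()]
#' @return object of the same kind as `Y0`
#' @export
setGeneric("interpolateWarmingLevel",
           function(Y0, Y1, spec) standardGeneric("interpolateWarmingLevel"))

.interpWeights <- function(spec) {
  if (spec$x1 == spec$x0) stop("degenerate spec: x1 equals x0")
  c(w0 = (spec$x1 - spec$x) / (spec$x1 - spec$x0),
    w1 = (spec$x - spec$x0) / (spec$x1 - spec$x0))
}

#' @rdname interpolateWarmingLevel
#' @export
setMethod("interpolateWarmingLevel", signature("ANY", "ANY"),
  function(Y0, Y1, spec) {
    if (!is.numeric(Y0) || !is.numeric(Y1))
      stop("Y0 and Y1 must be numeric fields or cropSCS climate objects")
    if (!identical(dim(Y0), dim(Y1))) stop("Y0 and Y1 are misaligned")
    w <- .interpWeights(spec)
    Y0 * w[["w0"]] + Y1 * w[["w1"]]
  })

#' @rdname interpolateWarmingLevel
#' @export
setMethod("interpolateWarmingLevel",
          signature("MonthlyClimatology", "MonthlyClimatology"),
  function(Y0, Y1, spec) {
    stopifnot(climVariable(Y0) == climVariable(Y1))
    .checkAligned(Y0, Y1)
    w <- .interpWeights(spec)
    new("MonthlyClimatology", variable = Y0@variable,
        values = Y0@values * w[["w0"]] + Y1@values * w[["w1"]])
  })

#' @rdname interpolateWarmingLevel
#' @export
setMethod("interpolateWarmingLevel", signature("HLZParamSet", "HLZParamSet"),
  function(Y0, Y1, spec) {
    .checkAligned(Y0, Y1)
    w <- .interpWeights(spec)
    mix <- function(a, b) a * w[["w0"]] + b * w[["w1"]]
    bt <- mix(Y0@biotemperature, Y1@biotemperature)
    frost <- mix(Y0@frostFree + 0, Y1@frostFree + 0) >= 0.5
    ap <- mix(Y0@annualPrecip, Y1@annualPrecip)
    cap <- max(Y0@aridityCap, Y1@aridityCap)
    new("HLZParamSet",
        annualPrecip = ap, biotemperature = bt,
        pet = HOLDRIDGE_PET_CONSTANT * bt,
        aridity = aridityIndex(HOLDRIDGE_PET_CONSTANT * bt, ap, cap = cap),
        frostFree = frost, aridityCap = cap)
  })

#' Compute the Holdridge life-zone parameter bundle
#'
#' Composes the parameter chain: monthly mean estimation from minima/maxima,
#' optional bias correction against a reference trio, then annual
#' precipitation, biotemperature, PET, aridity and the frost indicator.
#' Multi-year baseline inputs must be pre-averaged to a single monthly
#' climatology by the caller.
#'
#' @param tmin,tmax,precip `MonthlyClimatology` inputs on one grid
#' @param reference optional list(tmean, tmin, tmax) of reference
#'   climatologies for bias correction; NULL skips correction
#' @param aridityCap finite aridity substitute at zero precipitation
#' @param biotempCap optional monthly biotemperature clamp; `Inf` disables
#' @return an [HLZParamSet-class]
#' @export
computeHLZParams <- function(tmin, tmax, precip, reference = NULL,
                             aridityCap = 2^8, biotempCap = Inf) {
  .checkAligned(tmin, tmax, precip)
  tmean <- monthlyMeanEstimate(tmin, tmax)
  if (!is.null(reference))
    tmean <- biasCorrectTmean(tmean, reference$tmean, reference$tmin,
                              reference$tmax)
  bt <- biotemperature(tmean, biotempCap)
  ap <- annualPrecipitation(precip)
  pe <- HOLDRIDGE_PET_CONSTANT * bt
  new("HLZParamSet",
      annualPrecip = ap, biotemperature = bt, pet = pe,
      aridity = aridityIndex(pe, ap, cap = aridityCap),
      frostFree = frostIndicator(tmin), aridityCap = aridityCap)
}
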