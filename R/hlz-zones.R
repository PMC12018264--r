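#' @include climate.R
NULL

#' The 38-zone Holdridge life-zone edge table
#'
#' Versioned class-boundary table shipped with the package: seven
#' biotemperature belts on the log2 ladder (1.5, 3, 6, 12, 24 degC), the
#' frost indicator splitting the 12-24 degC belt into warm temperate
#' (frosty) and subtropical (frost-free), and log2 precipitation classes on
#' the 62.5 * 2^k ladder within each belt. All intervals are half-open
#' [low, high).
#'
#' @return data.frame with columns zone_id, zone_name, belt, tbio_low,
#'   tbio_high, frost_free, precip_low, precip_high
#' @export
hlzZoneTable <- function() {
  path <- system.file("extdata", "hlz_zones.csv", package = "cropSCS",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$frost_free <- as.logical(tab$frost_free)
  tab
}

#' Classify cells into the 38 Holdridge life zones
#'
#' Assigns each cell one of the 38 zones from its biotemperature belt,
#' frost indicator (only consulted in the 12-24 degC belt) and annual
#' precipitation class. Cells with any non-finite parameter are flagged
#' unclassified (NA).
#'
#' @param params an [HLZParamSet-class]
#' @param table zone edge table; defaults to the shipped [hlzZoneTable()]
#' @return integer matrix of zone ids in 1..38 (NA = unclassified)
#' @export
hlzClassify <- function(params, table = hlzZoneTable()) {
  bt <- params@biotemperature
  ap <- params@annualPrecip
  ff <- params@frostFree
  zone <- matrix(NA_integer_, nrow(bt), ncol(bt))
  ok <- is.finite(bt) & is.finite(ap) & !is.na(ff)
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    hit <- ok &
      bt >= r$tbio_low & bt < r$tbio_high &
      ap >= r$precip_low & ap < r$precip_high
    if (!is.na(r$frost_free)) hit <- hit & (ff == r$frost_free)
    zone[hit] <- r$zone_id
  }
  zone
}
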