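#' @include AllClasses.R
NULL

#' Default discretization of the Holdridge climate space
#'
#' Builds log2-spaced bin edges aligned with the Holdridge class geometry:
#' annual precipitation classes double from 62.5 mm/yr, biotemperature belts
#' double from 1.5 degC, aridity (humidity province) classes double across
#' 2^-5..2^8. Each Holdridge class is subdivided into `binsPerClass` equal
#' sub-bins in log2 space. The SCS envelope resolution depends on this
#' setting, so it is recorded in every SCSDefinition's provenance.
#'
#' @param binsPerClass number of sub-bins per Holdridge class per axis
#' @return a [ClimateBinning-class]
#' @export
climateBinning <- function(binsPerClass = 2) {
  stopifnot(is.finite(binsPerClass), binsPerClass >= 1)
  b <- 1 / binsPerClass
  new("ClimateBinning",
      precipEdges  = 62.5 * 2^seq(0, 7, by = b),
      biotempEdges = 1.5 * 2^seq(0, 4, by = b),
      aridityEdges = 2^seq(-5, 8, by = b),
      binsPerClass = binsPerClass)
}

#' Map values to half-open bins
#'
#' Bin i covers [edges[i], edges[i+1]); index 0 is the open bin below the
#' first edge and index length(edges) the open bin at/above the last, so
#' every finite value maps to exactly one bin. Non-finite values map to NA.
#'
#' @param x numeric vector
#' @param edges strictly increasing numeric edges
#' @return integer bin indices in 0..length(edges)
#' @export
binIndex <- function(x, edges) {
  idx <- findInterval(x, edges, left.open = FALSE, rightmost.closed = FALSE)
  idx[!is.finite(x)] <- NA_integer_
  idx
}

#' Bin keys for cells in the 4-axis climate space
#'
#' Encodes the (precipitation, biotemperature, aridity, frost) bin 4-tuple of
#' each cell as a single string key used as SCS set membership currency.
#' Cells with any non-finite parameter get NA.
#'
#' @param params an [HLZParamSet-class]
#' @param binning a [ClimateBinning-class]
#' @return character vector of length rows*cols (column-major cell order)
#' @export
binKey <- function(params, binning) {
  p <- binIndex(as.vector(params@annualPrecip), binning@precipEdges)
  b <- binIndex(as.vector(params@biotemperature), binning@biotempEdges)
  a <- binIndex(as.vector(params@aridity), binning@aridityEdges)
  f <- as.integer(as.vector(params@frostFree))
  key <- paste(p, b, a, f, sep = ":")
  key[is.na(p) | is.na(b) | is.na(a) | is.na(f)] <- NA_character_
  key
}

#' Coarsen a binning by merging adjacent sub-bins
#'
#' Keeps every `factor`-th edge (anchored at the first edge) on each axis.
#' Used to test the envelope monotonicity property: a coarser binning can
#' only grow, never shrink, the member set.
#'
#' @param binning a [ClimateBinning-class]
#' @param factor integer merge factor
#' @return a [ClimateBinning-class]
#' @export
coarsenBinning <- function(binning, factor = 2L) {
  keep <- function(e) e[seq(1L, length(e), by = factor)]
  new("ClimateBinning",
      precipEdges  = keep(binning@precipEdges),
      biotempEdges = keep(binning@biotempEdges),
      aridityEdges = keep(binning@aridityEdges),
      binsPerClass = binning@binsPerClass / factor)
}
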