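#' @include AllClasses.R scs.R
NULL

#' Write a single-band field as an ESRI ASCII grid
#'
#' Plain-text raster with the standard 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' row 1 first. NA becomes the NODATA value.
#'
#' @param field numeric or logical matrix
#' @param path output path (.asc)
#' @param xll,yll lower-left corner coordinates
#' @param cellsize cell size in the grid's units
#' @param nodata NODATA sentinel
#' @export
writeAsciiGrid <- function(field, path, xll = 0, yll = 0, cellsize = 1,
                           nodata = -9999) {
  v <- field
  mode(v) <- "numeric"
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(field)),
               sprintf("nrows %d", nrow(field)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  utils::write.table(format(v, trim = TRUE, digits = 15), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a .asc file
#' @return numeric matrix with attributes xll, yll, cellsize
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(x)
    stats::setNames(as.numeric(x[2L]), tolower(x[1L])))
  kv <- unlist(kv)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(kv)))
    stop("not an ESRI ASCII grid: ", path)
  v <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(v, nrow = kv[["nrows"]], ncol = kv[["ncols"]], byrow = TRUE)
  m[m == kv[["nodata_value"]]] <- NA
  attr(m, "xll") <- kv[["xllcorner"]]
  attr(m, "yll") <- kv[["yllcorner"]]
  attr(m, "cellsize") <- kv[["cellsize"]]
  m
}

#' Load several single-band rasters onto one reference grid
#'
#' Reads the listed ASCII grids and checks that every one shares the first
#' file's dimensions, origin and cell size; any mismatch is a hard error
#' naming the offending path (no silent resampling).
#'
#' @param paths character vector of .asc paths
#' @return named list of matrices
#' @export
loadAlignRasters <- function(paths) {
  out <- lapply(paths, readAsciiGrid)
  names(out) <- if (is.null(names(paths)))
    basename(paths) else names(paths)
  ref <- out[[1L]]
  refGeom <- c(dim(ref), attr(ref, "xll"), attr(ref, "yll"),
               attr(ref, "cellsize"))
  for (i in seq_along(out)[-1L]) {
    g <- c(dim(out[[i]]), attr(out[[i]], "xll"), attr(out[[i]], "yll"),
           attr(out[[i]], "cellsize"))
    if (!isTRUE(all.equal(refGeom, g)))
      stop("raster not aligned with reference grid: ", paths[i])
  }
  out
}

#' Write / read a monthly climatology as long-format CSV
#'
#' Columns variable, month, row, col, value; 12 months per cell.
#'
#' @param clim a `MonthlyClimatology`
#' @param path CSV path
#' @export
writeMonthlyCSV <- function(clim, path) {
  d <- dim(clim@values)
  df <- data.frame(variable = clim@variable,
                   month = rep(1:12, each = d[1L] * d[2L]),
                   row = rep(rep(seq_len(d[1L]), d[2L]), 12L),
                   col = rep(rep(seq_len(d[2L]), each = d[1L]), 12L),
                   value = as.vector(clim@values))
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname writeMonthlyCSV
#' @return `readMonthlyCSV`: a `MonthlyClimatology`
#' @export
readMonthlyCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "month", "row", "col", "value")
  if (!all(need %in% names(df))) stop("missing columns in ", path)
  if (!setequal(unique(df$month), 1:12))
    stop("monthly climatology must carry exactly months 1..12: ", path)
  R <- max(df$row); C <- max(df$col)
  arr <- array(NA_real_, c(R, C, 12L))
  arr[cbind(df$row, df$col, df$month)] <- df$value
  new("MonthlyClimatology", variable = df$variable[1L], values = arr)
}

#' Serialize an SCS definition to JSON
#'
#' Stores the binning edges, the occupied bin keys and the provenance
#' (captured share, cell counts, resolution) so a definition can be reused
#' or audited without the delineation inputs.
#'
#' @param scs an [SCSDefinition-class]
#' @param path JSON path
#' @export
writeSCSJson <- function(scs, path) {
  jsonlite::write_json(list(
    cropId = scs@cropId,
    binning = list(precipEdges = scs@binning@precipEdges,
                   biotempEdges = scs@binning@biotempEdges,
                   aridityEdges = scs@binning@aridityEdges,
                   binsPerClass = scs@binning@binsPerClass),
    occupied = scs@occupied,
    provenance = scs@provenance), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname writeSCSJson
#' @return `readSCSJson`: an [SCSDefinition-class]
#' @export
readSCSJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  binning <- new("ClimateBinning",
                 precipEdges = x$binning$precipEdges,
                 biotempEdges = x$binning$biotempEdges,
                 aridityEdges = x$binning$aridityEdges,
                 binsPerClass = x$binning$binsPerClass)
  new("SCSDefinition", cropId = x$cropId, binning = binning,
      occupied = x$occupied, provenance = as.list(x$provenance))
}

#' Write a synthetic-world bundle to a directory of plain-text files
#'
#' Climate as long-format CSV, crop production/area and masks as ESRI ASCII
#' grids, the true-niche set and the crop table as CSV.
#'
#' @param world a [SyntheticWorld-class]
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
writeWorldBundle <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (v in names(world@baseline)) {
    p <- file.path(dir, sprintf("baseline_%s.csv", v))
    writeMonthlyCSV(world@baseline[[v]], p)
    paths <- c(paths, p)
  }
  for (lv in names(world@futures))
    for (g in names(world@futures[[lv]]))
      for (v in names(world@futures[[lv]][[g]])) {
        p <- file.path(dir, sprintf("future_%s_%s_%s.csv", lv, g, v))
        writeMonthlyCSV(world@futures[[lv]][[g]][[v]], p)
        paths <- c(paths, p)
      }
  for (id in names(world@crops)) {
    p1 <- file.path(dir, sprintf("%s_production.asc", id))
    p2 <- file.path(dir, sprintf("%s_area.asc", id))
    writeAsciiGrid(production(world@crops[[id]]), p1)
    writeAsciiGrid(physicalArea(world@crops[[id]]), p2)
    paths <- c(paths, p1, p2)
  }
  p <- file.path(dir, "regions.asc")
  writeAsciiGrid(world@regions, p); paths <- c(paths, p)
  p <- file.path(dir, "elevation.asc")
  writeAsciiGrid(world@elevation, p); paths <- c(paths, p)
  p <- file.path(dir, "true_niches.csv")
  utils::write.csv(world@niches, p, row.names = FALSE); paths <- c(paths, p)
  crops <- data.frame(crop_id = names(world@crops),
                      food_crop = vapply(world@crops, foodFlag, logical(1L)),
                      group = vapply(world@crops, cropGroup, character(1L)))
  p <- file.path(dir, "crops.csv")
  utils::write.csv(crops, p, row.names = FALSE); paths <- c(paths, p)
  invisible(paths)
}
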