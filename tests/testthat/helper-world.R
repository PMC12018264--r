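# Shared fixtures, all built in code.

# Build an HLZParamSet directly from parameter matrices (pet/aridity derived).
makeParams <- function(biotemp, annualPrecip, frostFree = NULL,
                       aridityCap = 2^8) {
  if (is.null(frostFree))
    frostFree <- matrix(TRUE, nrow(biotemp), ncol(biotemp))
  pe <- 58.93 * biotemp
  new("HLZParamSet", annualPrecip = annualPrecip, biotemperature = biotemp,
      pet = pe, aridity = aridityIndex(pe, annualPrecip, cap = aridityCap),
      frostFree = frostFree, aridityCap = aridityCap)
}

# Uniform monthly climatology helper.
uniformClim <- function(variable, value, rows = 2, cols = 2) {
  MonthlyClimatology(variable, matrix(value, rows, cols))
}

# A small crop layer on a 1 x n grid from a production vector.
rowCrop <- function(p, id = "crop", area = NULL, group = "cereals") {
  if (is.null(area)) area <- ifelse(p > 0, 10, 0)
  new("CropLayer", cropId = id, production = matrix(p, 1),
      physicalArea = matrix(area, 1), foodFlag = TRUE, group = group)
}

# Cached synthetic worlds so expensive fixtures are built once per run.
.worldCache <- new.env(parent = emptyenv())
cachedWorld <- function(key, config) {
  if (is.null(.worldCache[[key]]))
    .worldCache[[key]] <- generateWorld(config)
  .worldCache[[key]]
}

smallWorld <- function() cachedWorld("small",
  worldConfig(gridRows = 40, gridCols = 60, nCrops = 3, nGcms = 3, seed = 11))

# Fixed, wide niches whose upper biotemperature bounds sit below the
# equatorial baseline biotemperature plus the strongest warming delta.
fixedNiches <- function() data.frame(
  crop = c("crop01", "crop02", "crop03"),
  tbioLow = c(10, 14, 6), tbioHigh = c(22, 25, 20),
  precipLow = c(300, 400, 250), precipHigh = c(2200, 2500, 1800),
  aridityMax = c(4, 4, 5))

# Decode "p:b:a:f" bin keys into an integer matrix.
decodeKeys <- function(keys) {
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  storage.mode(parts) <- "integer"
  colnames(parts) <- c("p", "b", "a", "f")
  parts
}
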