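#' @include climate.R scs.R
NULL

#' Configuration for the synthetic world generator
#'
#' Defines a small self-consistent world: a single-hemisphere grid running
#' from the equator (row 1) to the pole (last row), crops with known true
#' climatic niches, and pseudo-GCM futures that equal the baseline plus a
#' per-level temperature delta and precipitation scale factor plus seeded
#' per-GCM noise.
#'
#' @param gridRows,gridCols grid size (>= 1)
#' @param nCrops number of crops
#' @param nGcms number of pseudo-GCM ensemble members
#' @param warmingDeltas strictly increasing temperature offsets [deg C], one
#'   per warming level
#' @param precipScaleFactors multiplicative precipitation change per level
#'   (same length as `warmingDeltas`); default 1 - 0.02 x delta (mild drying
#'   with warming)
#' @param seed integer random seed; identical seeds give bit-identical worlds
#' @param noiseSdTemp white-noise standard deviation on monthly temperature
#'   [deg C] (also the per-GCM future noise)
#' @param noiseSdPrecipLog log-scale noise sd on monthly precipitation
#' @param marginalScatter fraction of each crop's total production placed on
#'   cells outside its true niche (exercises the lowest-5% marginal rule)
#' @param niches optional data.frame of true niches (crop, tbioLow, tbioHigh,
#'   precipLow, precipHigh, aridityMax); sampled if NULL
#' @return validated config list
#' @export
worldConfig <- function(gridRows = 60, gridCols = 120, nCrops = 6, nGcms = 4,
                        warmingDeltas = c(1.5, 2, 3, 4),
                        precipScaleFactors = 1 - 0.02 * warmingDeltas,
                        seed = 1L, noiseSdTemp = 0.3, noiseSdPrecipLog = 0.05,
                        marginalScatter = 0.02, niches = NULL) {
  num <- list(gridRows = gridRows, gridCols = gridCols, nCrops = nCrops,
              nGcms = nGcms, seed = seed, noiseSdTemp = noiseSdTemp,
              noiseSdPrecipLog = noiseSdPrecipLog,
              marginalScatter = marginalScatter)
  for (nm in names(num))
    if (length(num[[nm]]) != 1L || !is.finite(num[[nm]]))
      stop("config field '", nm, "' must be a single finite number")
  if (any(!is.finite(warmingDeltas)) || any(!is.finite(precipScaleFactors)))
    stop("config fields 'warmingDeltas'/'precipScaleFactors' must be finite")
  stopifnot(gridRows >= 1, gridCols >= 1, nCrops >= 1, nGcms >= 1,
            noiseSdTemp >= 0, noiseSdPrecipLog >= 0,
            marginalScatter >= 0, marginalScatter < 1)
  if (length(warmingDeltas) != length(precipScaleFactors))
    stop("warmingDeltas and precipScaleFactors must have the same length")
  if (length(warmingDeltas) > 1L && any(diff(warmingDeltas) <= 0))
    stop("warmingDeltas must be strictly increasing")
  list(gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
       nCrops = as.integer(nCrops), nGcms = as.integer(nGcms),
       warmingDeltas = warmingDeltas, precipScaleFactors = precipScaleFactors,
       seed = as.integer(seed), noiseSdTemp = noiseSdTemp,
       noiseSdPrecipLog = noiseSdPrecipLog, marginalScatter = marginalScatter,
       niches = niches)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Annual-mean precipitation [mm/yr] as a function of latitude: wet
# intertropical belt, dry subtropics, moderate mid-latitude storm track,
# dry poles.
.precipProfile <- function(lat) {
  knots <- c(0, 15, 22, 35, 50, 65, 80)
  vals <- c(2400, 1400, 450, 700, 950, 550, 300)
  stats::approx(knots, vals, xout = pmin(lat, 80), rule = 2)$y
}

#' Generate a synthetic world with known ground truth
#'
#' Builds a bundle of baseline monthly climate (latitudinal temperature
#' gradient plus seasonal sinusoid plus white noise; log-normal
#' precipitation around a latitudinal band structure), a zero-bias
#' reference trio, per-GCM per-level futures (baseline + delta x level +
#' per-GCM noise; precipitation scaled), crops whose production is positive
#' only inside their true niche except for a configured marginal scatter,
#' region masks, and an elevation field. Identical seeds give bit-identical
#' bundles.
#'
#' @param config a [worldConfig()]
#' @return a [SyntheticWorld-class]
#' @export
generateWorld <- function(config) {
  .withSeed(config$seed, {
    R <- config$gridRows; C <- config$gridCols
    ncell <- R * C
    lat <- seq(0, 80, length.out = R)              # row 1 = equator
    months <- 1:12

    annMean <- 28 - 0.55 * lat                     # deg C at sea level
    seasAmp <- 2 + 0.35 * lat                      # seasonality grows poleward
    lonMod <- 0.2 * sin(2 * pi * seq_len(C) / C)   # maritime/continental contrast

    tmean <- array(0, c(R, C, 12))
    for (m in months) {
      seas <- cos(2 * pi * (m - 7) / 12)
      tmean[, , m] <- outer(annMean + seasAmp * seas, 1 + lonMod) +
        matrix(stats::rnorm(ncell, 0, config$noiseSdTemp), R, C)
    }
    halfRange <- 4                                  # diurnal half-range [deg C]
    tminArr <- tmean - halfRange
    tmaxArr <- tmean + halfRange

    annP <- .precipProfile(lat)
    pr <- array(0, c(R, C, 12))
    monthW <- 1 + 0.3 * cos(2 * pi * (months - 7) / 12)  # mild wet season
    monthW <- monthW / sum(monthW)
    for (m in months) {
      noise <- stats::rnorm(ncell, -config$noiseSdPrecipLog^2 / 2,
                            config$noiseSdPrecipLog)
      pr[, , m] <- outer(annP * monthW[m], rep(1, C)) *
        matrix(exp(noise), R, C) *
        matrix(rep(exp(0.25 * sin(2 * pi * seq_len(C) / C)), each = R), R, C)
    }

    baseline <- list(
      tmin = new("MonthlyClimatology", variable = "tmin", values = tminArr),
      tmax = new("MonthlyClimatology", variable = "tmax", values = tmaxArr),
      precip = new("MonthlyClimatology", variable = "precip", values = pr))
    reference <- list(
      tmean = new("MonthlyClimatology", variable = "tmean",
                  values = (tminArr + tmaxArr) / 2),
      tmin = baseline$tmin, tmax = baseline$tmax)

    params <- computeHLZParams(baseline$tmin, baseline$tmax, baseline$precip,
                               reference = reference)

    niches <- config$niches
    if (is.null(niches))
      niches <- .sampleNiches(config$nCrops, params)
    crops <- .makeCrops(niches, params, config)

    futures <- list()
    for (i in seq_along(config$warmingDeltas)) {
      dT <- config$warmingDeltas[i]
      sP <- config$precipScaleFactors[i]
      lvl <- list()
      for (g in seq_len(config$nGcms)) {
        tNoise <- if (config$noiseSdTemp > 0)
          array(stats::rnorm(ncell * 12, 0, config$noiseSdTemp), c(R, C, 12))
        else array(0, c(R, C, 12))
        pNoise <- if (config$noiseSdPrecipLog > 0)
          array(exp(stats::rnorm(ncell * 12, -config$noiseSdPrecipLog^2 / 2,
                                 config$noiseSdPrecipLog)), c(R, C, 12))
        else array(1, c(R, C, 12))
        lvl[[paste0("gcm", g)]] <- list(
          tmin = new("MonthlyClimatology", variable = "tmin",
                     values = tminArr + dT + tNoise),
          tmax = new("MonthlyClimatology", variable = "tmax",
                     values = tmaxArr + dT + tNoise),
          precip = new("MonthlyClimatology", variable = "precip",
                       values = pr * sP * pNoise))
      }
      futures[[as.character(dT)]] <- lvl
    }

    regions <- matrix(cut(lat, c(-1, 25, 55, 90), labels = FALSE), R, C)
    regionNames <- c("low latitude", "mid latitude", "high latitude")

    elevation <- outer(seq_len(R), seq_len(C), function(r, c)
      pmax(0, 600 + 1400 * sin(r / R * 3 * pi) * cos(c / C * 4 * pi) +
             1800 * exp(-((r - R * 0.35)^2 + (c - C * 0.6)^2) / (0.01 * ncell)))) +
      matrix(abs(stats::rnorm(ncell, 0, 120)), R, C)

    new("SyntheticWorld", config = config, baseline = baseline,
        reference = reference, futures = futures, crops = crops,
        regions = regions, regionNames = regionNames, elevation = elevation,
        niches = niches)
  })
}

# Sample crop niches that are actually realized on the generated grid: draw
# biotemperature/precipitation windows around the realized parameter
# distribution until the niche covers a workable number of cells.
.sampleNiches <- function(nCrops, params) {
  bt <- as.vector(params@biotemperature)
  ap <- as.vector(params@annualPrecip)
  ar <- as.vector(params@aridity)
  rows <- list()
  for (k in seq_len(nCrops)) {
    for (try in 1:40) {
      lo <- stats::runif(1, 4, 20)
      hi <- lo + stats::runif(1, 6, 12)
      plo <- stats::runif(1, 250, 900)
      phi <- plo + stats::runif(1, 600, 1800)
      amax <- stats::runif(1, 1.5, 4)
      inside <- bt >= lo & bt <= hi & ap >= plo & ap <= phi & ar <= amax
      if (sum(inside) >= 30) break
    }
    rows[[k]] <- data.frame(crop = sprintf("crop%02d", k),
                            tbioLow = lo, tbioHigh = hi,
                            precipLow = plo, precipHigh = phi,
                            aridityMax = amax)
  }
  do.call(rbind, rows)
}

#' Cells inside a true niche
#'
#' @param niche one row of the true-niche table
#' @param params baseline [HLZParamSet-class]
#' @return logical matrix
#' @export
nicheContains <- function(niche, params) {
  params@biotemperature >= niche$tbioLow &
    params@biotemperature <= niche$tbioHigh &
    params@annualPrecip >= niche$precipLow &
    params@annualPrecip <= niche$precipHigh &
    params@aridity <= niche$aridityMax
}

.makeCrops <- function(niches, params, config) {
  R <- config$gridRows; C <- config$gridCols
  groups <- c("cereals", "pulses", "starchy roots", "oil crops",
              "fruits and vegetables")
  crops <- list()
  for (k in seq_len(nrow(niches))) {
    niche <- niches[k, ]
    inside <- nicheContains(niche, params)
    prod <- matrix(0, R, C)
    nIn <- sum(inside)
    if (nIn == 0) stop("true niche of '", niche$crop, "' covers no cell")
    prod[inside] <- stats::rlnorm(nIn, meanlog = 3, sdlog = 1)
    s <- config$marginalScatter
    if (s > 0) {
      outIdx <- which(!inside)
      nOut <- min(length(outIdx), max(1L, round(0.01 * R * C)))
      if (nOut > 0) {
        pick <- sample(outIdx, nOut)
        scatterTotal <- s / (1 - s) * sum(prod)
        w <- stats::runif(nOut)
        prod[pick] <- scatterTotal * w / sum(w)
      }
    }
    area <- matrix(0, R, C)
    hasProd <- prod > 0
    area[hasProd] <- stats::runif(sum(hasProd), 0, 100)  # nominal 100 ha cells
    # a few fallow cropland cells: area but no production
    fallow <- sample(which(!hasProd), max(1L, round(0.02 * R * C)))
    area[fallow] <- stats::runif(length(fallow), 0, 100)
    crops[[niche$crop]] <- new("CropLayer", cropId = niche$crop,
                               production = prod, physicalArea = area,
                               foodFlag = TRUE,
                               group = groups[(k - 1L) %% length(groups) + 1L])
  }
  crops
}

#' Total-cropland mask of a world
#'
#' Cells where any crop has production or physical area > 0.
#'
#' @param world a [SyntheticWorld-class], or a list of [CropLayer-class]
#' @return logical matrix
#' @export
totalCroplandMask <- function(world) {
  crops <- if (is(world, "SyntheticWorld")) worldCrops(world) else world
  Reduce(`|`, lapply(crops, function(cr)
    production(cr) > 0 | physicalArea(cr) > 0))
}

#' Total cropland physical area of a world
#'
#' Per-cell sum of physical cropland hectares across all crops.
#'
#' @inheritParams totalCroplandMask
#' @return numeric matrix [ha]
#' @export
totalCroplandArea <- function(world) {
  crops <- if (is(world, "SyntheticWorld")) worldCrops(world) else world
  Reduce(`+`, lapply(crops, physicalArea))
}

#' Ground-truth report: expected direction of SCS area change per level
#'
#' For each crop and warming level, flags whether the level's uniform
#' temperature delta pushes the warmest (equator-side) in-niche cells above
#' the niche's upper biotemperature bound (expected loss) and whether any
#' colder cell outside the niche is pushed into the biotemperature window
#' while satisfying the precipitation and aridity bounds (expected gain).
#' Negative deltas mirror the construction; a zero delta flags "none".
#'
#' @param world a [SyntheticWorld-class]
#' @return data.frame crop x level with expectedLoss, expectedGain, direction
#' @export
groundTruthReport <- function(world) {
  params <- computeHLZParams(world@baseline$tmin, world@baseline$tmax,
                             world@baseline$precip,
                             reference = world@reference)
  bt <- params@biotemperature
  rows <- list()
  for (k in seq_len(nrow(world@niches))) {
    niche <- world@niches[k, ]
    inside <- nicheContains(niche, params)
    btIn <- bt[inside]
    moistOk <- params@annualPrecip >= niche$precipLow &
      params@annualPrecip <= niche$precipHigh
    for (dT in c(0, world@config$warmingDeltas)) {
      if (dT > 0) {
        loss <- length(btIn) > 0 && max(btIn) + dT > niche$tbioHigh
        gain <- any(!inside & moistOk & bt < niche$tbioLow &
                      bt + dT >= niche$tbioLow & bt + dT <= niche$tbioHigh)
      } else if (dT < 0) {
        loss <- length(btIn) > 0 && min(btIn) + dT < niche$tbioLow
        gain <- any(!inside & moistOk & bt > niche$tbioHigh &
                      bt + dT <= niche$tbioHigh & bt + dT >= niche$tbioLow)
      } else {
        loss <- FALSE; gain <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        crop = niche$crop, delta = dT,
        expectedLoss = loss, expectedGain = gain,
        direction = if (!loss && !gain) "none"
                    else if (loss && !gain) "loss"
                    else if (gain && !loss) "gain" else "mixed")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
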