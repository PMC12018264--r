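test_that("monthly mean estimate is the min/max midpoint, cell- and month-wise", {
  tmin <- uniformClim("tmin", 10)
  tmax <- uniformClim("tmax", 20)
  tm <- monthlyMeanEstimate(tmin, tmax)
  expect_equal(climVariable(tm), "tmean")
  expect_true(all(climValues(tm) == 15))

  same <- monthlyMeanEstimate(uniformClim("tmin", 7),
                              MonthlyClimatology("tmax", matrix(7, 2, 2)))
  expect_true(all(climValues(same) == 7))
  sym <- monthlyMeanEstimate(uniformClim("tmin", -5), uniformClim("tmax", 5))
  expect_true(all(climValues(sym) == 0))

  expect_error(monthlyMeanEstimate(uniformClim("tmin", 1, rows = 3),
                                   uniformClim("tmax", 2, rows = 4)),
               "misaligned")
})

test_that("bias correction adds the reference offset and is not idempotent", {
  est <- uniformClim("tmean", 10)
  refTmin <- uniformClim("tmin", 0)
  refTmax <- uniformClim("tmax", 10)
  zeroRef <- uniformClim("tmean", 5)  # equals the midpoint: zero bias
  expect_equal(climValues(biasCorrectTmean(est, zeroRef, refTmin, refTmax)),
               climValues(est))

  # reference mean exceeds its midpoint by 0.7 degC in month 3 only
  v <- array(5, c(2, 2, 12)); v[, , 3] <- 5.7
  biasedRef <- new("MonthlyClimatology", variable = "tmean", values = v)
  out <- biasCorrectTmean(est, biasedRef, refTmin, refTmax)
  expect_equal(climValues(out)[, , 3], matrix(10.7, 2, 2))
  expect_equal(climValues(out)[, , 1], matrix(10, 2, 2))

  twice <- biasCorrectTmean(out, biasedRef, refTmin, refTmax)
  expect_equal(climValues(twice)[, , 3], matrix(11.4, 2, 2))

  v[1, 1, 5] <- NA
  holey <- new("MonthlyClimatology", variable = "tmean", values = v)
  expect_error(biasCorrectTmean(est, holey, refTmin, refTmax), "missing")
})

test_that("annual precipitation sums the twelve monthly fields", {
  expect_true(all(annualPrecipitation(uniformClim("precip", 100)) == 1200))
  expect_true(all(annualPrecipitation(uniformClim("precip", 0)) == 0))
  series <- MonthlyClimatology("precip", 1:12, dim = c(2, 2))
  expect_true(all(annualPrecipitation(series) == 78))
  bad <- new("MonthlyClimatology", variable = "tmean",
             values = array(-1, c(2, 2, 12)))
  bad@variable <- "precip"  # bypass constructor validity to hit the op check
  expect_error(annualPrecipitation(bad), "negative")
})

test_that("biotemperature clamps sub-zero months and divides by 12", {
  expect_true(all(biotemperature(uniformClim("tmean", 20)) == 20))
  halfhalf <- MonthlyClimatology("tmean", rep(c(10, -10), each = 6),
                                 dim = c(2, 2))
  expect_true(all(biotemperature(halfhalf) == 5))
  expect_true(all(biotemperature(uniformClim("tmean", -3)) == 0))
  # optional monthly cap
  expect_true(all(biotemperature(uniformClim("tmean", 35), biotempCap = 30) == 30))
})

test_that("Holdridge PET is 58.93 x biotemperature", {
  expect_true(all(abs(annualPET(uniformClim("tmean", 20)) - 1178.6) < 1e-9))
  expect_true(all(annualPET(uniformClim("tmean", -5)) == 0))
  set.seed(42)
  for (i in 1:20) {
    tm <- MonthlyClimatology("tmean", rnorm(12, 10, 12), dim = c(3, 4))
    bt <- biotemperature(tm)
    pe <- annualPET(tm)
    pos <- bt > 0
    expect_true(all(abs(pe[pos] / bt[pos] - 58.93) <= 1e-9 * 58.93))
  }
})

test_that("aridity is PET/precip with documented zero handling", {
  expect_equal(aridityIndex(matrix(1000), matrix(500)), matrix(2))
  expect_equal(aridityIndex(matrix(0), matrix(500)), matrix(0))
  expect_equal(aridityIndex(matrix(10), matrix(0)), matrix(2^8))
  expect_equal(aridityIndex(matrix(0), matrix(0)), matrix(0))
  expect_error(aridityIndex(matrix(-1), matrix(1)), "non-negative")
})

test_that("frost indicator requires strictly positive minima in all months", {
  expect_true(all(frostIndicator(uniformClim("tmin", 2))))
  dip <- array(2, c(2, 2, 12)); dip[, , 1] <- -0.1
  expect_false(any(frostIndicator(new("MonthlyClimatology",
                                      variable = "tmin", values = dip))))
  atZero <- array(2, c(2, 2, 12)); atZero[, , 6] <- 0
  expect_false(any(frostIndicator(new("MonthlyClimatology",
                                      variable = "tmin", values = atZero))))
})

test_that("warming-level interpolation is exact at endpoints and linear", {
  spec0 <- warmingLevelSpec(1.5, "SSP1-2.6", x = 2031, x0 = 2031, x1 = 2051)
  Y0 <- matrix(runif(20), 4, 5); Y1 <- matrix(runif(20), 4, 5)
  expect_identical(interpolateWarmingLevel(Y0, Y1, spec0), Y0)
  mid <- warmingLevelSpec(2, "s", x = 2041, x0 = 2031, x1 = 2051)
  expect_equal(interpolateWarmingLevel(Y0, Y1, mid), (Y0 + Y1) / 2)

  # linearity against the two-point line at random interior years
  set.seed(5)
  for (x in round(runif(8, 2031, 2051))) {
    sp <- warmingLevelSpec(2, "s", x = x, x0 = 2031, x1 = 2051)
    w <- (x - 2031) / 20
    expect_equal(interpolateWarmingLevel(Y0, Y1, sp),
                 Y0 * (1 - w) + Y1 * w, tolerance = 1e-12)
  }

  # the 1.5 degC level's years: x0=2031, x1=2051, x=2033
  sp15 <- warmingLevelSpec(1.5, "SSP1-2.6", x = 2033, x0 = 2031, x1 = 2051)
  expect_equal(interpolateWarmingLevel(matrix(10), matrix(20), sp15),
               matrix(11))

  expect_error(warmingLevelSpec(2, "s", x = 2031, x0 = 2031, x1 = 2031),
               "earlier")
  degen <- list(level = 2, ssp = "s", x = 2031, x0 = 2031, x1 = 2031)
  expect_error(interpolateWarmingLevel(Y0, Y1, degen), "degenerate")
})

test_that("interpolating an HLZ bundle re-thresholds the frost flag at 0.5", {
  bt <- matrix(c(10, 20), 1)
  p0 <- makeParams(bt, matrix(1000, 1, 2),
                   frostFree = matrix(c(TRUE, FALSE), 1))
  p1 <- makeParams(bt + 2, matrix(900, 1, 2),
                   frostFree = matrix(c(FALSE, FALSE), 1))
  near0 <- warmingLevelSpec(2, "s", x = 2035, x0 = 2031, x1 = 2051)
  out <- interpolateWarmingLevel(p0, p1, near0)   # weight on p0 = 0.8
  expect_identical(frostFree(out)[1, ], c(TRUE, FALSE))
  near1 <- warmingLevelSpec(2, "s", x = 2049, x0 = 2031, x1 = 2051)
  expect_identical(frostFree(interpolateWarmingLevel(p0, p1, near1))[1, ],
                   c(FALSE, FALSE))
  expect_equal(pet(out), 58.93 * biotemp(out))
})

test_that("the composed parameter bundle is internally consistent", {
  w <- smallWorld()
  p <- computeHLZParams(worldBaseline(w)$tmin, worldBaseline(w)$tmax,
                        worldBaseline(w)$precip, reference = worldReference(w))
  expect_equal(pet(p), 58.93 * biotemp(p), tolerance = 1e-12)
  # equatorial rows are warm and wet: aridity below ~1 at the equator
  expect_lt(mean(aridity(p)[1, ]), 1)
  # a polar, all-subzero column gives zero biotemperature, PET and aridity
  frozen <- computeHLZParams(uniformClim("tmin", -12), uniformClim("tmax", -2),
                             uniformClim("precip", 30))
  expect_true(all(biotemp(frozen) == 0) && all(pet(frozen) == 0) &&
              all(aridity(frozen) == 0))
})

test_that("biotemperature and PET are monotone under cell-wise warming", {
  set.seed(9)
  for (i in 1:10) {
    vals <- array(rnorm(2 * 3 * 12, 5, 10), c(2, 3, 12))
    tm <- new("MonthlyClimatology", variable = "tmean", values = vals)
    warmer <- new("MonthlyClimatology", variable = "tmean",
                  values = vals + array(runif(72, 0, 3), c(2, 3, 12)))
    expect_true(all(biotemperature(warmer) >= biotemperature(tm)))
    expect_true(all(annualPET(warmer) >= annualPET(tm)))
  }
})
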