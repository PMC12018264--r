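test_that("major-cell selection takes the smallest production prefix reaching the share", {
  crop <- rowCrop(c(90, 9, 1))
  expect_equal(sort(selectMajorCells(crop, 0.95)), c(1L, 2L))
  # exhaustive check of all prefixes for the same example
  p <- c(90, 9, 1)
  prefixes <- sapply(1:3, function(k) sum(sort(p, decreasing = TRUE)[1:k]))
  expect_equal(min(which(prefixes >= 0.95 * sum(p))), 2L)

  expect_equal(selectMajorCells(rowCrop(c(0, 5, 0)), 0.5), 2L)
  expect_equal(sort(selectMajorCells(rowCrop(c(3, 0, 2, 1)), 1)), c(1L, 3L, 4L))
  expect_error(selectMajorCells(rowCrop(c(0, 0))), "zero total production")
  # ties broken by row-major cell order
  expect_equal(selectMajorCells(rowCrop(c(5, 5, 5, 5)), 0.5), c(1L, 2L))
})

test_that("marginal cells are the lowest-share complement, optionally with fallow cropland", {
  expect_equal(selectMarginalCells(rowCrop(c(90, 9, 1)), 0.05), 3L)
  uni <- rowCrop(rep(1, 100))
  expect_equal(selectMarginalCells(uni, 0.05), 96:100)
  # marginal production never exceeds the share of the total
  set.seed(3)
  for (i in 1:10) {
    p <- rlnorm(50, 2, 1.5)
    marg <- selectMarginalCells(rowCrop(p), 0.05)
    expect_lte(sum(p[marg]), 0.05 * sum(p))
  }
  # zero-production cropland cells join via the mask
  crop <- rowCrop(c(8, 1, 0, 0))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1)
  expect_equal(selectMarginalCells(crop, 0.2, croplandMask = mask), c(2L, 3L))
})

test_that("delineation collects occupied bins of major cells with provenance", {
  # all major cells share one climate -> a single occupied bin
  bt <- matrix(15, 1, 4); ap <- matrix(800, 1, 4)
  params <- makeParams(bt, ap)
  crop <- rowCrop(c(50, 30, 15, 5))
  scs <- delineateSCS(crop, params, climateBinning(), share = 0.95)
  expect_equal(length(occupiedBins(scs)), 1L)
  expect_gte(scsProvenance(scs)$capturedShare, 0.95)

  # a major cell with non-finite parameters is excluded and counted
  params2 <- makeParams(matrix(c(15, NA, 15, 15), 1), ap)
  scs2 <- delineateSCS(crop, params2, climateBinning())
  expect_equal(scsProvenance(scs2)$nDroppedNonFinite, 1L)

  # tiny extra production on a marginal cell does not change the bin set
  params3 <- makeParams(matrix(c(15, 18, 22, 9), 1), matrix(c(800, 900, 400, 1500), 1))
  base <- delineateSCS(rowCrop(c(80, 19, 0.5, 0.5)), params3, climateBinning())
  bumped <- delineateSCS(rowCrop(c(80, 19, 0.5001, 0.5)), params3, climateBinning())
  expect_identical(occupiedBins(base), occupiedBins(bumped))
})

test_that("membership equals a brute-force per-cell bin lookup", {
  set.seed(21)
  bt <- matrix(runif(2500, 0, 30), 50)
  ap <- matrix(rlnorm(2500, 6.5, 0.8), 50)
  ff <- matrix(runif(2500) > 0.4, 50)
  params <- makeParams(bt, ap, ff)
  crop <- new("CropLayer", cropId = "x",
              production = matrix(rlnorm(2500, 1, 2) * (runif(2500) > 0.5), 50),
              physicalArea = matrix(1, 50, 50), foodFlag = TRUE,
              group = "cereals")
  scs <- delineateSCS(crop, params, climateBinning())
  member <- scsMembership(params, scs)

  # independent oracle: count-of-edges binning and set lookup per cell
  edgeBin <- function(x, edges) sum(x >= edges)
  occ <- occupiedBins(scs)
  b <- scsBinning(scs)
  for (cell in sample(2500, 400)) {
    key <- paste(edgeBin(ap[cell], b@precipEdges),
                 edgeBin(bt[cell], b@biotempEdges),
                 edgeBin(aridity(params)[cell], b@aridityEdges),
                 as.integer(ff[cell]), sep = ":")
    expect_identical(member[cell], key %in% occ)
  }

  # climates beyond every bin edge are outside
  far <- makeParams(matrix(100, 1, 1), matrix(1e6, 1, 1))
  expect_false(scsMembership(far, scs)[1, 1])
})

test_that("baseline production is self-contained in the crop's own SCS", {
  w <- smallWorld()
  p <- computeHLZParams(worldBaseline(w)$tmin, worldBaseline(w)$tmax,
                        worldBaseline(w)$precip, reference = worldReference(w))
  for (crop in worldCrops(w)) {
    scs <- delineateSCS(crop, p, climateBinning())
    member <- scsMembership(p, scs)
    captured <- sum(production(crop)[member]) / sum(production(crop))
    expect_gte(captured, 0.95)
  }
})

test_that("membership is invariant to the arrangement of cells at delineation", {
  set.seed(8)
  n <- 400
  bt <- runif(n, 5, 28); ap <- rlnorm(n, 6.5, 0.6); ff <- runif(n) > 0.3
  prod <- rlnorm(n, 2, 1.5)
  perm <- sample(n)
  mk <- function(ix) {
    params <- makeParams(matrix(bt[ix], 20), matrix(ap[ix], 20),
                         matrix(ff[ix], 20))
    crop <- new("CropLayer", cropId = "x", production = matrix(prod[ix], 20),
                physicalArea = matrix(1, 20, 20), foodFlag = TRUE,
                group = "cereals")
    delineateSCS(crop, params, climateBinning())
  }
  expect_identical(occupiedBins(mk(seq_len(n))), occupiedBins(mk(perm)))
})

test_that("coarsening the binning never shrinks the member set", {
  w <- smallWorld()
  p <- computeHLZParams(worldBaseline(w)$tmin, worldBaseline(w)$tmax,
                        worldBaseline(w)$precip, reference = worldReference(w))
  crop <- worldCrops(w)[[1]]
  fine <- climateBinning(2)
  coarse <- coarsenBinning(fine, 2L)
  mFine <- scsMembership(p, delineateSCS(crop, p, fine))
  mCoarse <- scsMembership(p, delineateSCS(crop, p, coarse))
  expect_true(all(mCoarse[mFine]))
})

test_that("with zero marginal scatter the SCS hull stays within one bin of the true niche", {
  cfg <- worldConfig(gridRows = 40, gridCols = 60, nCrops = 2, nGcms = 1,
                     seed = 4, marginalScatter = 0, niches = fixedNiches()[1:2, ])
  w <- generateWorld(cfg)
  p <- computeHLZParams(worldBaseline(w)$tmin, worldBaseline(w)$tmax,
                        worldBaseline(w)$precip, reference = worldReference(w))
  b <- climateBinning()
  for (k in 1:2) {
    niche <- trueNiches(w)[k, ]
    scs <- delineateSCS(worldCrops(w)[[k]], p, b)
    bins <- decodeKeys(occupiedBins(scs))
    # occupied bin ranges must sit within a one-bin dilation of the niche box
    expect_gte(min(bins[, "b"]), binIndex(niche$tbioLow, b@biotempEdges) - 1L)
    expect_lte(max(bins[, "b"]), binIndex(niche$tbioHigh, b@biotempEdges) + 1L)
    expect_gte(min(bins[, "p"]), binIndex(niche$precipLow, b@precipEdges) - 1L)
    expect_lte(max(bins[, "p"]), binIndex(niche$precipHigh, b@precipEdges) + 1L)
    expect_lte(max(bins[, "a"]), binIndex(niche$aridityMax, b@aridityEdges) + 1L)
  }
})
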