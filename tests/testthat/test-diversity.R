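test_that("cropland area within an SCS sums member-cell hectares", {
  area <- matrix(c(10, 20, 30, 40), 2)
  expect_equal(croplandAreaWithinSCS(matrix(FALSE, 2, 2), area), 0)
  expect_equal(croplandAreaWithinSCS(matrix(TRUE, 2, 2), area), 100)
  half <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(croplandAreaWithinSCS(half, matrix(25, 2, 2)), 50)
})

test_that("net change percentage follows the area-ratio definition", {
  expect_equal(netChangePct(100, 100), 0)
  expect_equal(netChangePct(50, 100), -50)
  expect_equal(netChangePct(120, 100), 20)
  expect_true(is.na(netChangePct(10, 0)))
})

test_that("gain and loss ratios satisfy the net-change identity", {
  area <- matrix(1, 10, 10)
  mb <- matrix(rep(c(TRUE, FALSE), 50), 10)
  same <- gainLossRatios(mb, mb, area)
  expect_equal(same$gainPct, 0)
  expect_equal(same$lossPct, 0)

  flipped <- gainLossRatios(mb, !mb, area)
  expect_equal(flipped$lossPct, 100)
  expect_equal(flipped$gainPct, sum(area[!mb]) / sum(area[mb]) * 100)

  set.seed(31)
  for (i in 1:20) {
    m0 <- matrix(runif(100) > 0.4, 10)
    m1 <- matrix(runif(100) > 0.6, 10)
    a <- matrix(rlnorm(100, 3, 1), 10)
    gl <- gainLossRatios(m0, m1, a)
    expect_equal(gl$gainPct - gl$lossPct,
                 netChangePct(gl$aWarming, gl$aBaseline), tolerance = 1e-9)
    expect_equal(gl$aWarming, gl$aBaseline + gl$aGain - gl$aLoss)
  }
})

test_that("group area statistics aggregate components before taking ratios", {
  ch <- data.frame(crop = c("a", "a", "b", "b"), gcm = c(1, 2, 1, 2),
                   aBaseline = c(100, 100, 100, 100),
                   aGain = c(10, 20, 10, 20), aLoss = c(30, 10, 30, 10))
  solo <- groupAreaStats(ch[ch$crop == "a", ], c(a = "g"))
  expect_equal(solo$netMedian, median(c(-20, 10)))
  both <- groupAreaStats(ch, c(a = "g", b = "g"))
  # identical member crops: group ratios equal the per-crop ratios
  expect_equal(both$netMedian, solo$netMedian)
  expect_equal(both$gainMedian, solo$gainMedian)
})

test_that("potential diversity counts match a brute-force recount", {
  set.seed(17)
  d <- c(20, 20)
  crops <- paste0("c", 1:7)
  cons <- lapply(crops, function(i) matrix(runif(400) > 0.5, 20))
  names(cons) <- crops
  mask <- matrix(runif(400) > 0.2, 20)
  cnt <- potentialDiversity(cons, mask)
  for (cell in sample(400, 100)) {
    manual <- sum(vapply(cons, function(m) m[cell], logical(1)))
    if (mask[cell]) expect_equal(cnt[cell], manual)
    else expect_true(is.na(cnt[cell]))
  }
  expect_true(all(cnt[mask] == 7 | cnt[mask] < 7))
  # monotone under adding a crop
  more <- c(cons, list(extra = matrix(TRUE, 20, 20)))
  expect_true(all(potentialDiversity(more, mask)[mask] >= cnt[mask]))
})

test_that("diversity-change categories implement the stated bin system", {
  base <- matrix(c(4, 0, 0, 2, 3, 4, 1, 8, 4), 3)
  lvl  <- matrix(c(2, 3, 0, 2, 0, 1, 3, 6, 5), 3)
  cats <- classifyDiversityChange(base, lvl)
  legend <- diversityCategoryLegend()
  lab <- function(r, c) legend$label[legend$code == cats[r, c]]
  expect_equal(lab(1, 1), "(-75%, -50%]")     # 4 -> 2 = -50%
  expect_equal(lab(2, 1), "cropland with emerging climatic potential")
  expect_equal(lab(3, 1),
               "marginal in baseline and outside SCS under warming level")
  expect_equal(lab(1, 2), "no change")
  expect_equal(lab(2, 2), "-100%")            # 3 -> 0
  expect_equal(lab(3, 2), "(-100%, -75%]")    # 4 -> 1 = -75%
  expect_equal(lab(1, 3), "> +75%")           # 1 -> 3 = +200%
  expect_equal(lab(2, 3), "(-50%, -25%]")     # 8 -> 6 = -25%
  expect_equal(lab(3, 3), "(0%, +25%]")       # 4 -> 5 = +25%
  expect_error(classifyDiversityChange(matrix(-1), matrix(1)), "non-negative")

  # exhaustive on cropland: every non-NA cell gets exactly one category
  set.seed(23)
  b2 <- matrix(rpois(100, 2), 10)
  l2 <- matrix(rpois(100, 2), 10)
  expect_false(anyNA(classifyDiversityChange(b2, l2)))
})

test_that("zonal category shares sum to one within each zone", {
  cats <- matrix(c(6, 6, 1, 11), 2)
  zones <- matrix(c(1L, 1L, 2L, 2L), 2)
  area <- matrix(c(30, 10, 5, 5), 2)
  tab <- zonalCategorySummary(cats, zones, area)
  z1 <- tab[tab$zone == "1", ]
  expect_equal(z1$areaShare[z1$code == 6], 1)
  z2 <- tab[tab$zone == "2", ]
  expect_equal(z2$areaShare[z2$code == 1], 0.5)
  expect_equal(z2$areaShare[z2$code == 11], 0.5)
  for (z in unique(tab$zone))
    expect_equal(sum(tab$areaShare[tab$zone == z]), 1, tolerance = 1e-9)

  # permuting zone labels permutes rows only
  swapped <- zonalCategorySummary(cats, matrix(c(2L, 2L, 1L, 1L), 2), area)
  expect_equal(swapped$areaShare[swapped$zone == "2"], z1$areaShare)
})

test_that("group diversity restricts the crop set and handles edge groups", {
  cons <- list(a = matrix(c(TRUE, FALSE), 1), b = matrix(c(TRUE, TRUE), 1))
  mask <- matrix(TRUE, 1, 2)
  all <- groupDiversity(cons, cons, c("a", "b"), mask)
  expect_equal(all$baseCount, potentialDiversity(cons, mask))
  expect_error(groupDiversity(cons, cons, character(0), mask), "empty")

  # single-crop group: only -100%, no change, emerging or marginal-outside
  base <- list(a = matrix(c(TRUE, TRUE, FALSE, FALSE), 1))
  lvl <- list(a = matrix(c(TRUE, FALSE, TRUE, FALSE), 1))
  g <- groupDiversity(base, lvl, "a", matrix(TRUE, 1, 4))
  expect_equal(as.vector(g$categories), c(6L, 1L, 11L, 12L))
})

test_that("elevation bands partition the grid with the high band isolated", {
  elev <- matrix(c(100, 600, 2000, 3000), 2)
  bands <- elevationBands(elev)
  expect_equal(names(bands), c("<500m", "500-1500m", "1500-2500m", ">2500m"))
  expect_equal(Reduce(`+`, lapply(bands, sum)), 4)
  expect_true(bands[[">2500m"]][2, 2])
})
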