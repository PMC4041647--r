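test_that("distance to river matches the brute-force oracle and examples", {
  # a river cell is at distance zero from itself
  m <- matrix(FALSE, 21, 21); m[11, ] <- TRUE
  d <- distanceToRiver(m, cellSize = 100)
  expect_equal(gridValues(d)[11, 5], 0)
  # three columns away at 100 m cells -> 300 m
  m2 <- matrix(FALSE, 5, 8); m2[, 2] <- TRUE
  expect_equal(gridValues(distanceToRiver(m2, 100))[3, 5], 300)
  # (3, 4) cell offset -> 3-4-5 triangle -> 500 m
  m3 <- matrix(FALSE, 10, 10); m3[2, 2] <- TRUE
  expect_equal(gridValues(distanceToRiver(m3, 100))[5, 6], 500)
  # exact agreement with the O(N*R) double loop on a random mask
  set.seed(42)
  m4 <- matrix(runif(30 * 40) < 0.03, 30, 40)
  m4[7, 9] <- TRUE  # guarantee non-empty
  expect_equal(gridValues(distanceToRiver(m4, 50)), bruteDistance(m4, 50))
  expect_error(distanceToRiver(matrix(FALSE, 5, 5)), "no river")
})

test_that("landscape generation is deterministic and validates input", {
  a <- generateLandscape(c(25, 30), seed = 3)
  b <- generateLandscape(c(25, 30), seed = 3)
  for (nm in floodpalm:::landscapeLayerNames())
    expect_identical(gridValues(slot(a, nm)), gridValues(slot(b, nm)))
  c <- generateLandscape(c(25, 30), seed = 4)
  expect_false(identical(gridValues(a@elevation), gridValues(c@elevation)))
  expect_error(generateLandscape(c(10, 30), seed = 1), "20 x 20")
  expect_error(
    generateLandscape(c(25, 30), landscapeParams(labelNoise = 1), seed = 1),
    "labelNoise")
})

test_that("zero label noise reproduces the rule labels exactly", {
  stk <- generateLandscape(c(30, 40), seed = 7)
  suit <- classifyRaster(stk)
  expect_identical(gridValues(suit), gridValues(stk@productivity))
})

test_that("label-noise rate is realised at the requested fraction", {
  # 10,000 cells at eps = 0.1: disagreement fraction 0.10 +/- 0.01
  p <- landscapeParams(labelNoise = 0.1)
  stk <- generateLandscape(c(100, 100), p, seed = 5)
  clean <- classifyRaster(stk)
  frac <- mean(gridValues(stk@productivity) != gridValues(clean))
  expect_lt(abs(frac - 0.10), 0.01)
})

test_that("elevation rises with river distance in expectation", {
  stk <- generateLandscape(c(50, 60), seed = 9)
  d <- as.vector(gridValues(stk@distRiver))
  e <- as.vector(gridValues(stk@elevation))
  bins <- cut(d, breaks = quantile(d, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  means <- tapply(e, bins, mean)
  expect_true(all(diff(means) > 0))
})

test_that("flood-prone extent grows with the flood-extent control", {
  lowFrac <- function(fs) {
    stk <- generateLandscape(c(40, 50),
                             landscapeParams(floodScale = fs), seed = 11)
    mean(gridValues(stk@elevation) <= 16 &
         gridValues(stk@distRiver) <= 1504)
  }
  fr <- vapply(c(500, 1500, 4000), lowFrac, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("parcel maps respect the smallholding cap and determinism", {
  pm <- generateParcels(c(40, 50), seed = 2)
  p <- pm@parcels
  expect_true(all(p$areaHa[p$title == "NT"] < 40))
  expect_false(anyDuplicated(p$id) > 0)
  expect_lte(sum(p$areaHa), 40 * 50)            # 1-ha cells
  pm2 <- generateParcels(c(40, 50), seed = 2)
  expect_identical(pm@parcels, pm2@parcels)
  bad <- landscapeParams(parcels = list(nNT = 2, ntSize = c(30, 45),
                                        nCL = 1, clSize = c(100, 200),
                                        nSD = 1, sdSize = c(20, 40)))
  expect_error(generateParcels(c(40, 50), bad, seed = 1), "40 ha")
  # rasterized titles cover exactly the parcel cells
  ras <- rasterizeParcels(pm)
  inParcel <- sum((p$rowMax - p$rowMin + 1) * (p$colMax - p$colMin + 1))
  expect_equal(sum(gridValues(ras) != titleCodes[["state_undemarcated"]]),
               inParcel)
})
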