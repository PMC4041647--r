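test_that("rounding is half-up at the reported precision", {
  expect_equal(roundHalfUp(0.5), 1)
  expect_equal(roundHalfUp(2.5), 3)
  expect_equal(roundHalfUp(-2.5), -3)
  expect_equal(roundHalfUp(63.499), 63)
  expect_equal(roundHalfUp(63.5), 64)
  expect_equal(roundHalfUp(1.25, 1), 1.3)
})

test_that("raster cross-tabulation conserves area", {
  a <- rasterGrid(matrix(1, 100, 100), categories = 1L)
  b <- rasterGrid(matrix(2, 100, 100), categories = 2L)
  tab <- crosstabArea(a, b)
  expect_equal(unname(tab$grandTotal), 10000)       # one 10,000-ha cell
  expect_equal(dim(tab$cells), c(1, 1))

  set.seed(4)
  av <- matrix(sample(1:3, 400, TRUE), 20, 20)
  bv <- matrix(sample(1:2, 400, TRUE), 20, 20)
  av[1, 1] <- NA                                    # nodata excluded
  ga <- rasterGrid(av, categories = 1:3)
  gb <- rasterGrid(bv, categories = 1:2)
  tab2 <- crosstabArea(ga, gb)
  expect_equal(sum(tab2$cells), tab2$grandTotal)
  expect_equal(rowSums(tab2$cells), tab2$rowTotals)
  expect_equal(colSums(tab2$cells), tab2$colTotals)
  expect_equal(unname(tab2$grandTotal), 399 * 1)    # cells x cell area
  # margins equal layer-wise class areas (over jointly valid cells)
  ok <- !is.na(av)
  expect_equal(unname(tab2$rowTotals),
               unname(as.vector(table(av[ok]))) * 1)
  # swapped arguments transpose the table
  tab3 <- crosstabArea(gb, ga)
  expect_equal(tab3$cells, t(tab2$cells))
  # misalignment is an error
  small <- rasterGrid(matrix(1, 10, 10), categories = 1L)
  expect_error(crosstabArea(ga, small), "aligned")
})

test_that("percentage shares reproduce the reported arithmetic", {
  expect_equal(percentShare(c(9497, 9732), 30173), 64)
  expect_equal(percentShare(c(5832, 5780, 2213, 6006), 30173), 66)
  expect_equal(percentShare(100, 100), 100)
  expect_error(percentShare(5, 0), "denominator")
})

test_that("combined redundancy is a monotone sum", {
  expect_equal(combinedRedundancy(15810, 16207), 32017)
  expect_equal(combinedRedundancy(0, 123), 123)
  expect_gte(combinedRedundancy(15810, 16207), 16207)
  expect_error(combinedRedundancy(-1, 5), "non-negative")
})

test_that("packaged reference tables carry the printed values", {
  t3 <- tableFixture("table3")
  expect_equal(t3$area_ha[t3$title == "NT"], 9497)
  # entries sum to within the known 2-ha transcription slack of the
  # printed 30,173 total
  expect_lte(abs(sum(t3$area_ha) - 30173), 2)

  t5 <- tableFixture("table5")
  expect_lte(abs(t5$grandTotal - 250617), 2)
  expect_equal(unname(t5$rowTotals["up25"]), 15810)

  t1 <- tableFixture("table1")
  mang <- t1$unprotected_ha[t1$system == "mangrove"]
  expect_equal(sum(mang), 655 + 506 + 1219 + 3282)  # 5,662

  t4 <- tableFixture("table4")
  expect_equal(sum(t4$suitability$cells), sum(t4$forestSystems$cells))
  expect_error(tableFixture("table99"))
})
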