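test_that("the default yield curve meets every stated constraint", {
  y <- as.numeric(defaultYieldCurve())
  expect_length(y, 25)
  expect_equal(y[1:2], c(0, 0))
  expect_equal(y[8:11], rep(30, 4))           # peak plateau
  expect_equal(y[25], 17)
  expect_equal(mean(y), 21.92)                # exact by construction
  expect_equal(sum(y), 548)
  expect_true(all(diff(y[2:8]) > 0))          # monotone ramp to peak
  expect_true(all(diff(y[11:25]) < 0))        # monotone decline
  expect_true(all(y >= 0))
  expect_error(yieldCurve(rep(1, 24)), "25")
  expect_error(yieldCurve(c(-1, rep(1, 24))), "non-negative")
})

test_that("capacity scaling is plain proportionality", {
  y <- defaultYieldCurve()
  expect_equal(as.numeric(scaleYield(y, 1)), as.numeric(y))
  expect_equal(as.numeric(scaleYield(y, 0)), rep(0, 25))
  expect_equal(as.numeric(scaleYield(y, 0.5))[8], 15)
  expect_error(scaleYield(y, 1.2), "capacity")
})

test_that("cash flows follow the three-category cost structure", {
  zero <- costSchedule(0, 0, 0, 0)
  sc <- economicScenario(capacity = 1)
  expect_equal(as.numeric(cashFlows(yieldCurve(rep(0, 25)), zero, sc)),
               rep(0, 25))
  # at full capacity the supplying term vanishes in years 1-2
  cs <- costSchedule(100, 200, 10, supplyingBase = 500)
  f1 <- cashFlows(scaleYield(defaultYieldCurve(), 1), cs, sc)
  expect_equal(as.numeric(f1)[1], -300)
  # hand arithmetic: yield 10 t, price 178, harvest 20/t, fixed 500
  cs2 <- costSchedule(500, 0, 20, supplyingBase = 0)
  f2 <- cashFlows(yieldCurve(rep(10, 25)), cs2,
                  economicScenario(capacity = 1))
  expect_equal(as.numeric(f2)[10], 178 * 10 - 20 * 10 - 500)  # 1080
  # supplying is charged at (1 - capacity) in years 1-2 only
  sc5 <- economicScenario(capacity = 0.5)
  f3 <- cashFlows(scaleYield(yieldCurve(rep(0, 25)), 0.5),
                  costSchedule(0, 0, 0, supplyingBase = 100), sc5)
  expect_equal(as.numeric(f3), c(-50, -50, rep(0, 23)))
})

test_that("npv matches hand-discounted cases and the rate-zero limit", {
  expect_equal(npv(rep(0, 25), 0.11)$npvTotal, 0)
  single <- c(100, rep(0, 24))
  expect_equal(npv(single, 0.11)$npvTotal, 100 / 1.11)
  flows <- c(-500, -200, rep(300, 23))
  expect_equal(npv(flows, 0)$npvTotal, sum(flows))
  r <- npv(flows, 0.08)
  expect_equal(r$npvAnnualized, r$npvTotal / 25)
  expect_error(npv(flows, -1.5), "-1")
})

test_that("calibration reproduces both anchors and the affine structure", {
  costs <- calibrateCosts()
  y <- defaultYieldCurve()
  expect_lt(abs(annualizedNPV(1.00, y, costs) - 637), 0.5)
  expect_lt(abs(annualizedNPV(0.76, y, costs) - 413), 0.5)
  # two-point line oracle: NPV(c) = slope * c + intercept
  slope <- (637 - 413) / (1 - 0.76)
  intercept <- 637 - slope
  for (cc in c(0, 0.25, 0.26, 0.5, 0.51, 0.75))
    expect_equal(annualizedNPV(cc, y, costs), slope * cc + intercept,
                 tolerance = 1e-9)
  # the supplying base cancels out of on-line predictions
  costsA <- calibrateCosts(supplyingBase = 0)
  costsB <- calibrateCosts(supplyingBase = 300)
  for (cc in c(0, 0.5, 1))
    expect_equal(annualizedNPV(cc, y, costsA),
                 annualizedNPV(cc, y, costsB), tolerance = 1e-9)
  expect_error(calibrateCosts(anchorHigh = c(1, 1e6)), "infeasible")
  expect_error(calibrateCosts(anchorLow = c(1, 413)), "distinct")
})

test_that("sensitivity is monotone in rate and capacity, break-even bracketed", {
  costs <- calibrateCosts()
  sens <- sensitivityTable(costs = costs)
  fullStand <- unlist(sens[sens$capacity == 1,
                           c("rate_5", "rate_8", "rate_11", "rate_14")])
  expect_true(all(diff(fullStand) < 0))       # decreasing in rate
  zeroCap <- unlist(sens[sens$capacity == 0, -1])
  expect_true(all(zeroCap < 0))               # negative at every rate
  for (col in c("rate_5", "rate_8", "rate_11", "rate_14"))
    expect_true(all(diff(sens[[col]]) >= -1e-9))  # non-decreasing in capacity
  be <- breakevenCapacity(costs = costs)
  expect_gt(be, 0.26); expect_lt(be, 0.50)
  # line oracle root
  slope <- (637 - 413) / 0.24
  expect_lt(abs(be - (slope - 637) / slope), 1e-3)
  y <- defaultYieldCurve()
  expect_lt(annualizedNPV(be - 0.05, y, costs), 0)
  expect_gt(annualizedNPV(be + 0.05, y, costs), 0)
  expect_lt(abs(annualizedNPV(be, y, costs)), 0.01)
  expect_error(breakevenCapacity(costs = costsNoSign <-
    costSchedule(0, 0, 0, 0)), "sign change")
})

test_that("productivity classes carry the nominal capacity bounds", {
  pc <- productivityClasses()
  expect_equal(pc$capacityLow[pc$class == "full_stand"], 0.76)
  expect_equal(pc$capacityHigh[pc$class == "up75"], 0.75)
  expect_equal(pc$capacityLow[pc$class == "up25"], 0)
  tab <- classNPVTable()
  expect_equal(tab$npvHigh[tab$class == "full_stand"], 637, tolerance = 1e-6)
})
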