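test_that("the floodplain rules classify the canonical points", {
  rs <- floodplainRuleset()
  cl <- function(d, e, s)
    applyRuleset(rs, distRiver = d, elevation = e, soil = s)
  expect_equal(cl(1000, 20, 3), "redundant")    # rule 1
  expect_equal(cl(2000, 15, 2), "redundant")    # rule 2
  expect_equal(cl(2000, 12, 4), "redundant")    # rule 3
  expect_equal(cl(5000, 30, 4), "full_stand")   # default
  # boundary semantics: <= keeps the threshold point inside the rule
  expect_equal(cl(1504, 22.4, 1), "redundant")
  expect_equal(cl(1504.01, 20, 3), "full_stand")
  expect_equal(cl(2000, 9.9, 4), "redundant")
  expect_equal(cl(2000, 9.89, 4), "full_stand")
  # exhaustive and deterministic: exactly one class per point
  pts <- expand.grid(distRiver = seq(0, 5000, 250),
                     elevation = seq(0, 40, 2), soil = 1:4)
  lab <- applyRuleset(rs, distRiver = pts$distRiver,
                      elevation = pts$elevation, soil = pts$soil)
  expect_true(all(lab %in% c("full_stand", "redundant")))
})

test_that("raster classification propagates nodata and flags missing layers", {
  flat <- function(v, cats = NULL) rasterGrid(matrix(v, 20, 20),
                                              categories = cats)
  stack <- list(distRiver = flat(1000), elevation = flat(20),
                soil = flat(3, 1:4))
  out <- classifyRaster(stack)
  expect_true(all(gridValues(out) == suitabilityCodes[["redundant"]]))
  high <- list(distRiver = flat(3000), elevation = flat(35),
               soil = flat(3, 1:4))
  expect_true(all(gridValues(classifyRaster(high)) ==
                  suitabilityCodes[["full_stand"]]))
  ev <- matrix(20, 20, 20); ev[1, 1] <- NA
  stack$elevation <- rasterGrid(ev)
  expect_true(is.na(gridValues(classifyRaster(stack))[1, 1]))
  expect_error(classifyRaster(stack[c("distRiver", "elevation")]),
               "soil")
})

test_that("gini matches hand-computed impurities", {
  expect_equal(gini(rep("a", 10)), 0)
  expect_equal(gini(c("a", "a", "b", "b")), 0.5)
  # the 263 / 211 two-class training split
  expect_equal(gini(rep(c("full_stand", "redundant"), c(263, 211))),
               1 - (263 / 474)^2 - (211 / 474)^2)
  expect_error(gini(character(0)), "empty")
})

test_that("best split matches the exhaustive brute-force search", {
  d <- data.frame(x = c(1, 2, 10, 11))
  y <- c("A", "A", "B", "B")
  s <- bestSplit(d, y)
  expect_equal(s$var, "x")
  expect_equal(s$threshold, 6)
  expect_equal(s$decrease, 0.5)
  expect_null(bestSplit(d, rep("A", 4)))                 # pure
  expect_null(bestSplit(data.frame(x = c(1, 1)), c("A", "B")))  # degenerate
  # randomized agreement with the double-loop oracle
  set.seed(31)
  for (i in 1:10) {
    x <- data.frame(u = sample(1:8, 40, TRUE), v = round(runif(40), 2))
    y <- sample(c("p", "q"), 40, TRUE)
    got <- bestSplit(x, y)
    want <- bruteBestSplit(x, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$decrease, want$decrease, tolerance = 1e-10)
    }
  }
})

test_that("grown trees are consistent, pure on separable data", {
  d <- data.frame(x = c(1:10, 21:30))
  y <- rep(c("A", "B"), each = 10)
  tr <- growTree(d, y, minLeaf = 1)
  expect_equal(predict(tr, d), y)                        # zero training error
  pure <- growTree(data.frame(x = 1:10), rep("A", 10))
  expect_equal(floodpalm:::countLeaves(pure$root), 1L)
  # every split strictly reduces weighted impurity
  checkNode <- function(node, x, idx) {
    if (node$leaf) return(invisible(NULL))
    go <- x[[node$var]][idx] <= node$threshold
    gp <- gini(yAll[idx])
    gw <- (sum(go) * gini(yAll[idx[go]]) +
           sum(!go) * gini(yAll[idx[!go]])) / length(idx)
    expect_gt(gp - gw, 0)
    checkNode(node$left, x, idx[go])
    checkNode(node$right, x, idx[!go])
  }
  set.seed(17)
  xs <- data.frame(a = runif(200), b = runif(200))
  yAll <- ifelse(xs$a + 0.3 * xs$b + rnorm(200, 0, 0.1) > 0.6, "hi", "lo")
  checkNode(growTree(xs, yAll)$root, xs, seq_len(200))
})

test_that("noise-free training recovers the generating thresholds", {
  d <- generateTrainingSamples(5000, seed = 11)
  tr <- growTree(d[, 1:3], d$label)
  expect_equal(mean(predict(tr, d[, 1:3]) == d$label), 1)
  th <- treeThresholds(tr)
  near <- function(target, var, tol) any(abs(th[[var]] - target) <= tol)
  expect_true(near(1504, "distRiver", 20))   # one distance-grid step
  expect_true(near(1947, "distRiver", 20))
  expect_true(near(22.4, "elevation", 0.25)) # one elevation-grid step
  expect_true(near(16, "elevation", 0.25))
  expect_true(near(9.9, "elevation", 0.25))
  expect_true(near(14, "elevation", 0.25))
})

test_that("the root split agrees with an independent CART implementation", {
  d <- generateTrainingSamples(2000, seed = 5)
  mine <- growTree(d[, 1:3], d$label)
  fit <- rpart::rpart(label ~ distRiver + elevation + soil, d,
                      method = "class",
                      control = rpart::rpart.control(cp = 1e-4,
                                                     minbucket = 5))
  rootVar <- as.character(fit$frame$var[1])
  rootThr <- fit$splits[1, "index"]
  expect_equal(mine$root$var, rootVar)
  expect_lt(abs(mine$root$threshold - rootThr),
            if (rootVar == "distRiver") 21 else 0.26)
})

test_that("extracted rules reproduce the tree exactly", {
  # depth-1 tree reads out as a single elevation rule
  d1 <- data.frame(elevation = c(seq(10, 22, 1), 22.3, 22.5, seq(23, 35, 1)))
  y1 <- ifelse(d1$elevation <= 22.4, "redundant", "full_stand")
  t1 <- growTree(d1, y1, minLeaf = 1)
  r1 <- extractRules(t1)
  expect_length(r1$rules, 1)
  expect_equal(r1$rules[[1]]$conditions[[1]]$var, "elevation")
  expect_equal(r1$rules[[1]]$conditions[[1]]$value, 22.4)
  expect_equal(r1$default, "full_stand")
  # semantic round trip on a dense grid of points
  d <- generateTrainingSamples(3000, seed = 23)
  tr <- growTree(d[, 1:3], d$label)
  rs <- extractRules(tr)
  pts <- expand.grid(distRiver = seq(0, 5000, 100),
                     elevation = seq(0, 40, 0.5), soil = 1:4)
  expect_identical(
    applyRuleset(rs, distRiver = pts$distRiver,
                 elevation = pts$elevation, soil = pts$soil),
    predict(tr, pts))
  # soil conditions are reported as class sets
  soilConds <- unlist(lapply(rs$rules, function(r)
    lapply(r$conditions, function(cc) if (cc$var == "soil") cc$op)))
  expect_true(all(soilConds == "in"))
})

test_that("CV pruning keeps optimal trees and collapses pure noise", {
  # cleanly separable data: pruning leaves the perfect tree intact
  d <- data.frame(x = c(1:20, 41:60))
  y <- rep(c("A", "B"), each = 20)
  tr <- growTree(d, y)
  pr <- pruneTreeCV(tr, d, y, seed = 1)
  expect_equal(predict(pr, d), y)
  expect_gte(pr$cv$accuracy, 0)
  expect_lte(pr$cv$accuracy, 1)
  # pure-noise labels collapse to (near) the root in most seeds; the
  # one-SE rule cannot guarantee collapse in every replicate
  leaves <- vapply(1:20, function(s) {
    set.seed(s)
    x <- data.frame(a = runif(300), b = runif(300))
    yy <- sample(c("p", "q"), 300, replace = TRUE)
    pt <- pruneTreeCV(growTree(x, yy), x, yy, seed = s)
    floodpalm:::countLeaves(pt$root)
  }, integer(1))
  expect_gte(mean(leaves == 1L), 0.7)
  expect_equal(median(leaves), 1)
  # determinism given the seed
  d2 <- generateTrainingSamples(800, seed = 3, labelNoise = 0.1)
  p1 <- pruneTreeCV(growTree(d2[, 1:3], d2$label), d2[, 1:3], d2$label,
                    seed = 9)
  p2 <- pruneTreeCV(growTree(d2[, 1:3], d2$label), d2[, 1:3], d2$label,
                    seed = 9)
  expect_identical(p1$root, p2$root)
})

test_that("pruned trees recover the rules from noisy training data", {
  d <- generateTrainingSamples(2000, seed = 41, labelNoise = 0.05)
  pt <- pruneTreeCV(growTree(d[, 1:3], d$label), d[, 1:3], d$label,
                    seed = 41)
  test <- generateTrainingSamples(4000, seed = 4100)
  expect_gte(mean(predict(pt, test[, 1:3]) == test$label), 0.95)
})
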