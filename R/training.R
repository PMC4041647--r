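#' Generate labelled suitability training samples
#'
#' Draws point training data over the predictor space the suitability
#' classifier operates on: distance to river, elevation and soil class are
#' sampled uniformly from regular design grids and labelled by a rule set
#' (by default the flood-driven rules of [floodplainRuleset()]), with an
#' optional fraction of labels flipped at random. Sampling from discrete
#' grids mirrors raster-extracted training points and bounds how far a
#' recovered split threshold can sit from the generating one: split
#' midpoints land within one grid step of the true boundary.
#'
#' When \code{stratify} is TRUE (the default) the draw is stratified over
#' the partition of the predictor space induced by the rule thresholds:
#' every (soil class, distance interval, elevation interval) cell of the
#' partition receives an equal share of the samples, with the cell's
#' corner grid values pinned before the random fill. Every decision
#' boundary is then flanked at the adjacent grid values on both sides even
#' where a rule region is small, so a recovered split threshold sits
#' within one grid step of the generating one; uniform sampling leaves
#' the rarer regions too sparse for that.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param labelNoise fraction of labels flipped, in [0, 1).
#' @param rules labelling \code{RuleSet}.
#' @param distGrid,elevGrid design grids for distance (m) and elevation
#'   (m ASL); defaults span 0-5,000 m in 20 m steps and 0-40 m in
#'   0.25 m steps.
#' @param soilClasses admissible soil codes.
#' @param stratify stratify over the rule-induced partition (default)
#'   rather than sampling uniformly.
#' @return data.frame with columns distRiver, elevation, soil, label.
#' @export
generateTrainingSamples <- function(n, seed, labelNoise = 0,
                                    rules = floodplainRuleset(),
                                    distGrid = seq(0, 5000, by = 20),
                                    elevGrid = seq(0, 40, by = 0.25),
                                    soilClasses = 1:4, stratify = TRUE) {
  if (labelNoise < 0 || labelNoise >= 1)
    stop("labelNoise must lie in [0, 1)")
  withSeed(seed, {
    d <- if (stratify)
      .stratifiedDesign(n, rules, distGrid, elevGrid, soilClasses)
    else
      data.frame(
        distRiver = sample(distGrid, n, replace = TRUE),
        elevation = sample(elevGrid, n, replace = TRUE),
        soil = as.numeric(sample(soilClasses, n, replace = TRUE)))
    d$label <- applyRuleset(rules, distRiver = d$distRiver,
                            elevation = d$elevation, soil = d$soil)
    if (labelNoise > 0) {
      flip <- runif(n) < labelNoise
      other <- ifelse(d$label == "redundant", "full_stand", "redundant")
      d$label[flip] <- other[flip]
    }
    d
  })
}

# thresholds a ruleset places on one variable, in increasing order
ruleThresholds <- function(rules, var) {
  vals <- unlist(lapply(rules$rules, function(r)
    vapply(Filter(function(cc) cc$var == var && cc$op != "in",
                  r$conditions),
           function(cc) cc$value, numeric(1))))
  sort(unique(vals))
}

# equal allocation over the (soil x dist-interval x elev-interval) cells
# of the partition the rule thresholds induce
.stratifiedDesign <- function(n, rules, distGrid, elevGrid, soilClasses) {
  cutGrid <- function(grid, breaks)
    split(grid, findInterval(grid, breaks, left.open = TRUE))
  distCells <- cutGrid(distGrid, ruleThresholds(rules, "distRiver"))
  elevCells <- cutGrid(elevGrid, ruleThresholds(rules, "elevation"))
  cells <- expand.grid(soil = seq_along(soilClasses),
                       dc = seq_along(distCells),
                       ec = seq_along(elevCells))
  per <- rep(n %/% nrow(cells), nrow(cells))
  extra <- sample.int(nrow(cells), n %% nrow(cells))
  per[extra] <- per[extra] + 1L
  pick <- function(pool, k) pool[sample.int(length(pool), k,
                                            replace = TRUE)]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    k <- per[i]
    if (k == 0) return(NULL)
    dp <- distCells[[cells$dc[i]]]
    ep <- elevCells[[cells$ec[i]]]
    # pin the cell corners first: the grid values flanking each rule
    # threshold are then always present on both sides of every boundary
    corners <- expand.grid(distRiver = range(dp), elevation = range(ep))
    corners <- corners[!duplicated(corners), , drop = FALSE]
    nc <- min(k, nrow(corners))
    d <- data.frame(
      distRiver = c(corners$distRiver[seq_len(nc)], pick(dp, k - nc)),
      elevation = c(corners$elevation[seq_len(nc)], pick(ep, k - nc)))
    d$soil <- as.numeric(soilClasses[cells$soil[i]])
    d
  })
  do.call(rbind, out)
}

#' Sample training points from a landscape stack
#'
#' Extracts predictor values and productivity labels at randomly chosen
#' cells of a [LandscapeStack-class] — the raster analogue of extracting
#' point training data from mapped full-stand and redundant areas.
#'
#' @param stack a [LandscapeStack-class].
#' @param n number of cells to sample.
#' @param seed integer seed.
#' @return data.frame with distRiver, elevation, soil, label.
#' @export
sampleStackTraining <- function(stack, n, seed) {
  ncell <- prod(dim(stack@elevation@values))
  withSeed(seed, {
    idx <- sample.int(ncell, min(n, ncell))
    data.frame(
      distRiver = as.vector(stack@distRiver@values)[idx],
      elevation = as.vector(stack@elevation@values)[idx],
      soil = as.vector(stack@soil@values)[idx],
      label = codeName(suitabilityCodes,
                       as.vector(stack@productivity@values)[idx]))
  })
}

#' Train and prune a suitability tree
#'
#' Convenience wrapper: grows a CART on the three informative predictors
#' and prunes it by 10-fold cross-validation.
#'
#' @param samples data.frame with distRiver, elevation, soil, label.
#' @param minLeaf,maxDepth tree-growing controls (see [growTree()]).
#' @param folds,seed cross-validation controls (see [pruneTreeCV()]).
#' @return a CV-pruned \code{palmCART}.
#' @export
trainSuitabilityTree <- function(samples, minLeaf = 5, maxDepth = 10,
                                 folds = 10, seed = 1) {
  x <- samples[, c("distRiver", "elevation", "soil")]
  tree <- growTree(x, samples$label, minLeaf = minLeaf,
                   maxDepth = maxDepth)
  pruneTreeCV(tree, x, samples$label, folds = folds, seed = seed)
}
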