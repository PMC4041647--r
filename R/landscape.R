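#' Default parameters for the synthetic floodplain generator
#'
#' Returns the parameter list consumed by [generateLandscape()] and
#' [generateParcels()]. The defaults describe a meandering lowland river
#' whose floodplain rises gently away from the channel, with patchy soil
#' suitability and a land-title tessellation dominated by smallholdings
#' near the river and large commercial leases further out.
#'
#' @param riverSinuosity number of meander wavelengths across the grid.
#' @param riverAmplitude meander amplitude as a fraction of the grid height.
#' @param elevBase elevation of the channel banks, m ASL.
#' @param elevRange asymptotic elevation gain away from the river, m.
#' @param floodScale distance (m) at which half of \code{elevRange} is
#'   reached; larger values keep low-lying flood-prone land extending
#'   further from the channel.
#' @param noiseSd standard deviation (m) of the smoothed elevation noise.
#' @param smoothRadius box-smoothing radius (cells) for the noise fields.
#' @param soilPatchSize smoothing radius (cells) of the soil random field;
#'   larger values give larger soil patches.
#' @param labelNoise fraction of productivity cells whose label is flipped
#'   relative to the suitability rules, in [0, 1).
#' @param parcels a list with per-title parcel counts and size ranges (ha):
#'   \code{nNT}, \code{ntSize}, \code{nCL}, \code{clSize}, \code{nSD},
#'   \code{sdSize}. NT sizes must stay below 40 ha.
#' @param cellSize cell side in meters; the default 100 m makes 1-ha cells.
#' @return a named list of parameters.
#' @export
landscapeParams <- function(riverSinuosity = 1.5, riverAmplitude = 0.25,
                            elevBase = 3, elevRange = 35, floodScale = 1500,
                            noiseSd = 1.5, smoothRadius = 2,
                            soilPatchSize = 5, labelNoise = 0,
                            parcels = list(nNT = 40, ntSize = c(5, 39),
                                           nCL = 6, clSize = c(150, 450),
                                           nSD = 8, sdSize = c(20, 120)),
                            cellSize = 100) {
  list(riverSinuosity = riverSinuosity, riverAmplitude = riverAmplitude,
       elevBase = elevBase, elevRange = elevRange, floodScale = floodScale,
       noiseSd = noiseSd, smoothRadius = smoothRadius,
       soilPatchSize = soilPatchSize, labelNoise = labelNoise,
       parcels = parcels, cellSize = cellSize)
}

# run expr with a private, seeded RNG stream; user RNG state is untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# box blur with replicate-padded edges; separable, exact renormalisation
boxBlur <- function(m, radius) {
  if (radius < 1) return(m)
  r <- as.integer(radius)
  pad <- function(x) {
    n <- length(x)
    c(rep(x[1], r), x, rep(x[n], r))
  }
  blur1 <- function(x) {
    p <- pad(x)
    cs <- cumsum(p)
    w <- 2 * r + 1
    (cs[(w):(length(p))] - c(0, cs[seq_len(length(p) - w)])) / w
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

#' Euclidean distance to the river channel
#'
#' Exact cell-center Euclidean distance from every cell to the nearest
#' river cell: value at cell c is the minimum over river cells r of the
#' distance between the two cell centers, in meters. River cells map to 0.
#'
#' @param riverMask a logical matrix or a [RasterGrid-class] with values
#'   0/1 marking river cells.
#' @param cellSize cell side in meters (taken from the grid if a
#'   [RasterGrid-class] is supplied).
#' @return a continuous [RasterGrid-class] of distances in meters.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, ] <- TRUE
#' gridValues(distanceToRiver(m, cellSize = 100))[1, 1]  # 200 m
#' @export
distanceToRiver <- function(riverMask, cellSize = 100) {
  if (is(riverMask, "RasterGrid")) {
    cellSize <- riverMask@cellSize
    mask <- riverMask@values != 0
  } else {
    mask <- riverMask != 0
  }
  if (!any(mask, na.rm = TRUE))
    stop("river mask contains no river cells")
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  riv <- which(mask, arr.ind = TRUE)          # R x 2 (row, col)
  out <- matrix(0, nr, nc)
  # chunk over columns to bound the N x R intermediate
  chunk <- max(1L, floor(2e6 / nrow(riv)))
  for (j0 in seq(1L, nc, by = chunk)) {
    j1 <- min(nc, j0 + chunk - 1L)
    cols <- j0:j1
    cr <- rep(seq_len(nr), times = length(cols))
    cc <- rep(cols, each = nr)
    d2 <- outer(cr, riv[, 1], "-")^2 + outer(cc, riv[, 2], "-")^2
    out[, cols] <- matrix(sqrt(.rowMins(d2)), nr, length(cols))
  }
  rasterGrid(out * cellSize, cellSize = cellSize)
}

.rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), na.rm = TRUE))
}

#' Generate a synthetic floodplain landscape
#'
#' Builds a complete, mutually aligned raster stack emulating a tropical
#' river floodplain: a meandering channel, elevation rising (in
#' expectation) with distance from the channel, patchy soil-suitability
#' classes, forest systems stratified by elevation and river proximity, a
#' land-title tessellation (via [generateParcels()]) and a palm-productivity
#' layer labelled by the flood-driven suitability rules
#' ([floodplainRuleset()]) with optional label noise.
#'
#' All randomness flows from the single integer seed; identical
#' \code{(shape, params, seed)} give bit-identical stacks. Aspect and slope
#' layers are generated as pure noise: they deliberately carry no
#' suitability signal.
#'
#' @param shape integer (rows, cols), at least 20 x 20.
#' @param params parameter list from [landscapeParams()].
#' @param seed single integer seed.
#' @return a [LandscapeStack-class].
#' @examples
#' stk <- generateLandscape(c(30, 40), seed = 1)
#' stk
#' @export
generateLandscape <- function(shape, params = landscapeParams(), seed) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 20))
    stop("shape must be at least 20 x 20")
  eps <- params$labelNoise
  if (!is.numeric(eps) || eps < 0 || eps >= 1)
    stop("labelNoise must lie in [0, 1)")
  nr <- shape[1]; nc <- shape[2]
  cs <- params$cellSize
  withSeed(seed, {
    # -- river channel: one meandering cell-wide path west to east
    phase <- runif(1, 0, 2 * pi)
    centre <- nr / 2 +
      params$riverAmplitude * nr *
        sin(2 * pi * params$riverSinuosity * seq_len(nc) / nc + phase)
    rows <- pmin(nr, pmax(1L, round(centre)))
    mask <- matrix(FALSE, nr, nc)
    for (j in seq_len(nc)) {
      # connect vertically so the channel is 8-connected
      r0 <- if (j == 1) rows[j] else rows[j - 1]
      mask[seq(min(r0, rows[j]), max(r0, rows[j])), j] <- TRUE
    }
    dist <- distanceToRiver(mask, cellSize = cs)
    d <- dist@values

    # -- elevation: saturating ramp away from the channel + smoothed noise
    noise <- boxBlur(matrix(rnorm(nr * nc), nr, nc), params$smoothRadius)
    noise <- noise / stats::sd(noise) * params$noiseSd
    elev <- params$elevBase +
      params$elevRange * d / (d + params$floodScale) + noise
    elev <- pmax(elev, 0)

    # -- soil: smoothed random field cut at quartiles -> patchy classes 1-4
    field <- boxBlur(matrix(rnorm(nr * nc), nr, nc), params$soilPatchSize)
    q <- stats::quantile(field, c(0.25, 0.5, 0.75))
    soil <- matrix(1L + findInterval(field, q), nr, nc)

    # -- aspect / slope: signal-free by construction
    aspect <- matrix(runif(nr * nc, 0, 360), nr, nc)
    slope <- abs(boxBlur(matrix(rnorm(nr * nc, 0, 2), nr, nc),
                         params$smoothRadius))

    # -- productivity: suitability rules + Bernoulli label noise
    lab <- applyRuleset(floodplainRuleset(),
                        distRiver = as.vector(d),
                        elevation = as.vector(elev),
                        soil = as.vector(soil))
    code <- suitabilityCodes[lab]
    if (eps > 0) {
      flip <- runif(nr * nc) < eps
      code[flip] <- 1L - code[flip]
    }
    prod <- matrix(as.integer(code), nr, nc)

    # -- forest system: elevation / proximity strata with degraded patches
    fs <- matrix(forestSystemCodes["lowland_dry"], nr, nc)
    fs[elev < 18] <- forestSystemCodes["seasonally_flooded"]
    fs[elev < 6 & d < 1200] <- forestSystemCodes["mangrove"]
    degr <- boxBlur(matrix(rnorm(nr * nc), nr, nc), params$soilPatchSize)
    fs[degr > stats::quantile(degr, 0.88)] <-
      forestSystemCodes["mixed_degraded"]
    fs[mask] <- forestSystemCodes["non_forest"]

    # -- land titles from the parcel tessellation
    pm <- .placeParcels(shape, params)
    titles <- rasterizeParcels(pm)

    new("LandscapeStack",
        elevation = rasterGrid(elev, cellSize = cs),
        distRiver = dist,
        soil = rasterGrid(soil, cellSize = cs, categories = 1:4),
        forestSystem = rasterGrid(fs, cellSize = cs,
                                  categories = unname(forestSystemCodes)),
        productivity = rasterGrid(prod, cellSize = cs,
                                  categories = unname(suitabilityCodes)),
        titles = titles,
        aspect = rasterGrid(aspect, cellSize = cs),
        slope = rasterGrid(slope, cellSize = cs))
  })
}

#' Generate a land-parcel tessellation
#'
#' Places non-overlapping rectangular parcels of three title types on the
#' grid: Native Title (NT) smallholdings strictly under 40 ha, Country Land
#' (CL) commercial leases, and demarcated State land. Cells outside every
#' parcel are undemarcated State land. Placement is seeded and
#' deterministic.
#'
#' @inheritParams generateLandscape
#' @return a [ParcelMap-class].
#' @export
generateParcels <- function(shape, params = landscapeParams(), seed) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 20))
    stop("shape must be at least 20 x 20")
  withSeed(seed, .placeParcels(shape, params))
}

.placeParcels <- function(shape, params) {
  pp <- params$parcels
  if (max(pp$ntSize) >= 40)
    stop("NT parcel sizes must be < 40 ha")
  nr <- shape[1]; nc <- shape[2]
  cellHa <- params$cellSize^2 / 1e4
  occupied <- matrix(FALSE, nr, nc)
  rows <- list()
  nextId <- 1L
  place <- function(n, sizeRange, title) {
    for (k in seq_len(n)) {
      targetHa <- runif(1, sizeRange[1], sizeRange[2])
      cells <- max(1L, floor(targetHa / cellHa))
      w <- max(1L, round(sqrt(cells) * runif(1, 0.7, 1.4)))
      h <- max(1L, floor(cells / w))
      if (w > nc || h > nr) next
      areaHa <- w * h * cellHa
      if (title == "NT" && areaHa >= 40) {  # rounding guard
        h <- h - 1L
        if (h < 1L) next
        areaHa <- w * h * cellHa
      }
      for (try in seq_len(60)) {
        r0 <- sample.int(nr - h + 1L, 1L)
        c0 <- sample.int(nc - w + 1L, 1L)
        block <- occupied[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
        if (!any(block)) {
          occupied[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <<- TRUE
          rows[[length(rows) + 1L]] <<- data.frame(
            id = nextId, title = title,
            rowMin = r0, rowMax = r0 + h - 1L,
            colMin = c0, colMax = c0 + w - 1L, areaHa = areaHa)
          nextId <<- nextId + 1L
          break
        }
      }
    }
  }
  place(pp$nCL, pp$clSize, "CL")
  place(pp$nSD, pp$sdSize, "state_demarcated")
  place(pp$nNT, pp$ntSize, "NT")
  parcels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), title = character(0), rowMin = integer(0),
               rowMax = integer(0), colMin = integer(0), colMax = integer(0),
               areaHa = numeric(0))
  new("ParcelMap", parcels = parcels, cellSize = params$cellSize,
      shape = shape)
}

#' Rasterize a parcel map into a land-title layer
#'
#' @param pm a [ParcelMap-class].
#' @return a categorical [RasterGrid-class] of title codes (see
#'   [titleCodes]); cells outside every parcel get the undemarcated-State
#'   code.
#' @export
rasterizeParcels <- function(pm) {
  m <- matrix(titleCodes[["state_undemarcated"]], pm@shape[1], pm@shape[2])
  p <- pm@parcels
  for (i in seq_len(nrow(p)))
    m[p$rowMin[i]:p$rowMax[i], p$colMin[i]:p$colMax[i]] <-
      titleCodes[[p$title[i]]]
  rasterGrid(m, cellSize = pm@cellSize, categories = unname(titleCodes))
}
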