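#' @import methods
NULL

#' RasterGrid: a single-layer regular raster
#'
#' A minimal in-memory raster layer: a rectangular matrix of cell values with
#' a fixed cell size, a top-left origin and a nodata sentinel. The default
#' cell size of 100 m means one cell is exactly one hectare, the resolution
#' at which all suitability predictors and area accounting operate.
#'
#' Coordinate convention (used throughout the package): row-major storage,
#' origin at the top-left corner, rows increase southwards and columns
#' eastwards, and all distances are measured between cell centers.
#'
#' Categorical layers store integer codes and declare the admissible codes in
#' the \code{categories} slot; the validity method rejects any other value.
#' Continuous layers leave \code{categories} empty.
#'
#' @slot values numeric matrix of cell values (NA marks nodata in memory).
#' @slot cellSize side length of a square cell in meters; 100 m = 1 ha cells.
#' @slot origin numeric of length 2, (x, y) of the top-left corner in meters.
#' @slot nodata numeric sentinel used when the layer is written to disk.
#' @slot categories integer vector of admissible codes for categorical
#'   layers; \code{integer(0)} for continuous layers.
#'
#' @seealso [rasterGrid()] for the user-facing constructor,
#'   [gridValues()], [cellSize()], [cellAreaHa()].
#' @export
setClass("RasterGrid",
  representation(
    values     = "matrix",
    cellSize   = "numeric",
    origin     = "numeric",
    nodata     = "numeric",
    categories = "integer"
  ),
  prototype(
    cellSize   = 100,
    origin     = c(0, 0),
    nodata     = -9999,
    categories = integer(0)
  )
)

setValidity("RasterGrid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "'cellSize' must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be two finite coordinates")
  if (length(object@nodata) != 1)
    msg <- c(msg, "'nodata' must be a single value")
  if (length(object@categories) > 0) {
    v <- object@values[!is.na(object@values)]
    if (length(v) && !all(v %in% object@categories))
      msg <- c(msg, "categorical grid contains undeclared category codes")
  }
  if (length(msg)) msg else TRUE
})

#' LandscapeStack: aligned raster layers of a floodplain landscape
#'
#' The full predictor and label stack the suitability analysis consumes:
#' elevation (m ASL), Euclidean distance to the main river (m), soil
#' agricultural-suitability class (1 = unsuitable, 2 = marginal,
#' 3 = suitable, 4 = very suitable), forest-system class, land-title class,
#' palm-productivity class, plus aspect and slope layers that are generated
#' but carry no suitability signal. All layers share shape, cell size and
#' origin; the validity method enforces the alignment.
#'
#' @slot elevation,distRiver continuous [RasterGrid] layers (m).
#' @slot soil categorical [RasterGrid], codes 1-4.
#' @slot forestSystem categorical [RasterGrid], see [forestSystemCodes].
#' @slot productivity categorical [RasterGrid], see [suitabilityCodes].
#' @slot titles categorical [RasterGrid], see [titleCodes].
#' @slot aspect,slope continuous [RasterGrid] layers (degrees); no signal.
#'
#' @seealso [generateLandscape()], [classifyRaster()]
#' @export
setClass("LandscapeStack",
  representation(
    elevation    = "RasterGrid",
    distRiver    = "RasterGrid",
    soil         = "RasterGrid",
    forestSystem = "RasterGrid",
    productivity = "RasterGrid",
    titles       = "RasterGrid",
    aspect       = "RasterGrid",
    slope        = "RasterGrid"
  )
)

setValidity("LandscapeStack", function(object) {
  msg <- character(0)
  layers <- lapply(landscapeLayerNames(), function(nm) slot(object, nm))
  ref <- layers[[1]]
  for (i in seq_along(layers)[-1]) {
    l <- layers[[i]]
    if (!identical(dim(l@values), dim(ref@values)))
      msg <- c(msg, sprintf("layer '%s' is not aligned in shape",
                            landscapeLayerNames()[i]))
    if (!identical(l@cellSize, ref@cellSize) ||
        !identical(l@origin, ref@origin))
      msg <- c(msg, sprintf("layer '%s' differs in cellSize or origin",
                            landscapeLayerNames()[i]))
  }
  soilv <- object@soil@values[!is.na(object@soil@values)]
  if (length(soilv) && !all(soilv %in% 1:4))
    msg <- c(msg, "soil layer must contain only classes 1-4")
  if (length(msg)) msg else TRUE
})

#' ParcelMap: a tessellation of land parcels with title types
#'
#' Parcels are axis-aligned rectangular blocks of cells, each carrying a
#' unique id, a land-title type and an area in hectares. Native Title (NT)
#' smallholdings are restricted to under 40 ha; Country Land (CL) parcels
#' are large commercial leases. Parcels never overlap; cells outside any
#' parcel are undemarcated State land.
#'
#' @slot parcels data.frame with columns id, title, rowMin, rowMax, colMin,
#'   colMax, areaHa.
#' @slot cellSize cell side in meters (shared with the raster layers).
#' @slot shape integer (rows, cols) of the underlying grid.
#' @export
setClass("ParcelMap",
  representation(
    parcels  = "data.frame",
    cellSize = "numeric",
    shape    = "integer"
  )
)

setValidity("ParcelMap", function(object) {
  p <- object@parcels
  msg <- character(0)
  need <- c("id", "title", "rowMin", "rowMax", "colMin", "colMax", "areaHa")
  if (!all(need %in% names(p)))
    return(paste("parcels must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$id)) msg <- c(msg, "parcel ids must be unique")
  if (!all(p$title %in% names(titleCodes)))
    msg <- c(msg, "unknown title type in parcels")
  nt <- p$areaHa[p$title == "NT"]
  if (length(nt) && any(nt >= 40))
    msg <- c(msg, "NT parcels must be < 40 ha")
  if (nrow(p) > 1) {
    # overlap check on the rectangle bounds
    for (i in seq_len(nrow(p) - 1)) {
      j <- (i + 1):nrow(p)
      ov <- p$rowMin[j] <= p$rowMax[i] & p$rowMax[j] >= p$rowMin[i] &
            p$colMin[j] <= p$colMax[i] & p$colMax[j] >= p$colMin[i]
      if (any(ov)) { msg <- c(msg, "parcels overlap"); break }
    }
  }
  if (length(msg)) msg else TRUE
})
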