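#' Construct a RasterGrid
#'
#' @param values numeric matrix of cell values; use NA for nodata.
#' @param cellSize cell side in meters (default 100, i.e. 1-ha cells).
#' @param origin (x, y) of the top-left corner.
#' @param nodata sentinel written to disk for NA cells.
#' @param categories admissible integer codes for a categorical layer, or
#'   NULL for a continuous layer.
#' @return a [RasterGrid-class] object.
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4), categories = 1:12)
#' cellAreaHa(g)
#' @export
rasterGrid <- function(values, cellSize = 100, origin = c(0, 0),
                       nodata = -9999, categories = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), nodata = as.numeric(nodata),
      categories = if (is.null(categories)) integer(0)
                   else as.integer(categories))
}

#' Raster accessors
#'
#' @param x a [RasterGrid-class].
#' @return \code{gridValues} the value matrix; \code{cellSize} the cell side
#'   in meters; \code{cellAreaHa} the area of one cell in hectares;
#'   \code{isCategorical} whether the layer declares category codes.
#' @name raster-accessors
NULL

#' @rdname raster-accessors
#' @export
gridValues <- function(x) x@values

#' @rdname raster-accessors
#' @export
cellSize <- function(x) x@cellSize

#' @rdname raster-accessors
#' @export
cellAreaHa <- function(x) x@cellSize^2 / 1e4

#' @rdname raster-accessors
#' @export
isCategorical <- function(x) length(x@categories) > 0

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("RasterGrid: %d x %d cells, %.0f m cells (%.2f ha)\n",
              d[1], d[2], object@cellSize, cellAreaHa(object)))
  v <- object@values[!is.na(object@values)]
  if (isCategorical(object)) {
    cat("  categorical, codes:", paste(object@categories, collapse = " "),
        "\n")
  } else if (length(v)) {
    cat(sprintf("  range: [%.3g, %.3g]\n", min(v), max(v)))
  }
  if (anyNA(object@values))
    cat(sprintf("  nodata cells: %d\n", sum(is.na(object@values))))
})

setMethod("show", "LandscapeStack", function(object) {
  d <- dim(object@elevation@values)
  cat(sprintf("LandscapeStack: %d x %d cells at %.0f m\n",
              d[1], d[2], object@elevation@cellSize))
  cat("  layers:", paste(landscapeLayerNames(), collapse = ", "), "\n")
})

setMethod("show", "ParcelMap", function(object) {
  cat(sprintf("ParcelMap: %d parcels on a %d x %d grid\n",
              nrow(object@parcels), object@shape[1], object@shape[2]))
  if (nrow(object@parcels))
    print(table(object@parcels$title))
})

landscapeLayerNames <- function() {
  c("elevation", "distRiver", "soil", "forestSystem", "productivity",
    "titles", "aspect", "slope")
}

#' Integer code tables for categorical layers
#'
#' Named integer vectors mapping class names to the raster codes used in
#' every categorical layer. The same tables are shipped as a CSV under
#' \code{inst/extdata/code_tables.csv}.
#'
#' \describe{
#'   \item{titleCodes}{land-title classes: Native Title (NT) smallholdings,
#'     Country Land (CL) commercial leases, demarcated and undemarcated
#'     State land.}
#'   \item{forestSystemCodes}{floodplain forest systems plus non-forest.}
#'   \item{soilCodes}{agricultural soil suitability, 1 (unsuitable) to
#'     4 (very suitable).}
#'   \item{suitabilityCodes}{palm productivity / suitability: 0 full_stand
#'     (suitable), 1 redundant (unsuitable, at or below 25\% palm
#'     capacity).}
#' }
#' @name codeTables
NULL

#' @rdname codeTables
#' @export
titleCodes <- c(NT = 1L, CL = 2L, state_demarcated = 3L,
                state_undemarcated = 4L)

#' @rdname codeTables
#' @export
forestSystemCodes <- c(mangrove = 1L, seasonally_flooded = 2L,
                       lowland_dry = 3L, mixed_degraded = 4L,
                       non_forest = 5L)

#' @rdname codeTables
#' @export
soilCodes <- c(unsuitable = 1L, marginal = 2L, suitable = 3L,
               very_suitable = 4L)

#' @rdname codeTables
#' @export
suitabilityCodes <- c(full_stand = 0L, redundant = 1L)

codeName <- function(codes, values) {
  names(codes)[match(values, codes)]
}
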