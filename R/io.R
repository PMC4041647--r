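#' Write a RasterGrid as an ESRI ASCII grid
#'
#' Plain-text ESRI ASCII grid (.asc): a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by one line per
#' raster row, north row first. Continuous values are written with 17
#' significant digits so the write/read round trip is lossless in double
#' precision; categorical codes are written as integers.
#'
#' @param grid a [RasterGrid-class].
#' @param path output file path (.asc).
#' @return the path, invisibly.
#' @export
writeAsciiGrid <- function(grid, path) {
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  yll <- grid@origin[2] - nr * grid@cellSize
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.17g", grid@origin[1]),
           sprintf("yllcorner %.17g", yll),
           sprintf("cellsize %.17g", grid@cellSize),
           sprintf("NODATA_value %.17g", grid@nodata))
  out <- v
  out[is.na(out)] <- grid@nodata
  fmt <- if (isCategorical(grid)) "%d" else "%.17g"
  lines <- apply(out, 1, function(row)
    paste(sprintf(fmt, if (fmt == "%d") as.integer(row) else row),
          collapse = " "))
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path .asc file path.
#' @param categories admissible codes if the layer is categorical.
#' @return a [RasterGrid-class]; cells equal to the file's NODATA value
#'   become NA.
#' @export
readAsciiGrid <- function(path, categories = NULL) {
  hdr <- readLines(path, n = 6)
  val <- function(i) as.numeric(strsplit(hdr[i], "\\s+")[[1]][2])
  nc <- as.integer(val(1)); nr <- as.integer(val(2))
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  v <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  rasterGrid(m, cellSize = cs, origin = c(xll, yll + nr * cs),
             nodata = nodata, categories = categories)
}

stackCategories <- function(layer) {
  switch(layer,
         soil = 1:4,
         forestSystem = unname(forestSystemCodes),
         productivity = unname(suitabilityCodes),
         titles = unname(titleCodes),
         NULL)
}

#' Write a landscape stack to a directory
#'
#' One ESRI ASCII grid per layer (named \code{<layer>.asc}), the code
#' tables as CSV, and optionally the parcel map as GeoJSON. The written
#' stack round-trips losslessly through [readStack()].
#'
#' @param stack a [LandscapeStack-class].
#' @param dir output directory (created if needed).
#' @param parcels optional [ParcelMap-class] written as
#'   \code{parcels.geojson}.
#' @return the directory, invisibly.
#' @export
writeStack <- function(stack, dir, parcels = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  for (nm in landscapeLayerNames())
    writeAsciiGrid(slot(stack, nm), file.path(dir, paste0(nm, ".asc")))
  codes <- data.frame(
    table = rep(c("titles", "forestSystem", "soil", "suitability"),
                times = c(length(titleCodes), length(forestSystemCodes),
                          length(soilCodes), length(suitabilityCodes))),
    name = c(names(titleCodes), names(forestSystemCodes), names(soilCodes),
             names(suitabilityCodes)),
    code = c(titleCodes, forestSystemCodes, soilCodes, suitabilityCodes))
  utils::write.csv(codes, file.path(dir, "code_tables.csv"),
                   row.names = FALSE)
  if (!is.null(parcels))
    writeParcelsGeoJSON(parcels, file.path(dir, "parcels.geojson"))
  invisible(dir)
}

#' Read a landscape stack from a directory
#'
#' @param dir directory written by [writeStack()].
#' @return a [LandscapeStack-class].
#' @export
readStack <- function(dir) {
  layers <- lapply(landscapeLayerNames(), function(nm)
    readAsciiGrid(file.path(dir, paste0(nm, ".asc")),
                  categories = stackCategories(nm)))
  names(layers) <- landscapeLayerNames()
  do.call(new, c(list("LandscapeStack"), layers))
}

#' Write a parcel map as GeoJSON
#'
#' Each parcel becomes a Polygon feature (rectangle in the grid's
#' projected coordinates, cell-edge aligned) with id, title type, area and
#' the grid bounds as properties, so the file round-trips losslessly
#' through [readParcelsGeoJSON()].
#'
#' @param pm a [ParcelMap-class].
#' @param path output path (.geojson).
#' @return the path, invisibly.
#' @export
writeParcelsGeoJSON <- function(pm, path) {
  cs <- pm@cellSize
  p <- pm@parcels
  features <- lapply(seq_len(nrow(p)), function(i) {
    x0 <- (p$colMin[i] - 1) * cs; x1 <- p$colMax[i] * cs
    y0 <- -(p$rowMin[i] - 1) * cs; y1 <- -p$rowMax[i] * cs
    list(type = "Feature",
         properties = list(id = p$id[i], title = p$title[i],
                           areaHa = p$areaHa[i],
                           rowMin = p$rowMin[i], rowMax = p$rowMax[i],
                           colMin = p$colMin[i], colMax = p$colMax[i]),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(cellSize = cs,
                               shape = as.integer(pm@shape)),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parcel map from GeoJSON
#'
#' @param path file written by [writeParcelsGeoJSON()].
#' @return a [ParcelMap-class].
#' @export
readParcelsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    pr <- f$properties
    data.frame(id = as.integer(pr$id), title = pr$title,
               rowMin = as.integer(pr$rowMin),
               rowMax = as.integer(pr$rowMax),
               colMin = as.integer(pr$colMin),
               colMax = as.integer(pr$colMax),
               areaHa = as.numeric(pr$areaHa))
  })
  parcels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), title = character(0), rowMin = integer(0),
               rowMax = integer(0), colMin = integer(0), colMax = integer(0),
               areaHa = numeric(0))
  new("ParcelMap", parcels = parcels,
      cellSize = as.numeric(gj$properties$cellSize),
      shape = as.integer(unlist(gj$properties$shape)))
}
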