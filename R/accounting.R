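#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every reported percentage:
#' 0.5 always rounds up in magnitude, unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Area cross-tabulation of two categorical layers
#'
#' Hectares per (class A, class B) pair over two aligned categorical
#' rasters. Cells that are nodata in either layer are excluded from all
#' totals; for the remainder the grand total equals cell count times cell
#' area exactly.
#'
#' @param layerA,layerB aligned categorical [RasterGrid-class] layers.
#' @param namesA,namesB optional named code vectors (e.g. [titleCodes])
#'   used to label the table dimensions.
#' @return an \code{AreaCrossTab}: list with \code{cells} (ha matrix),
#'   \code{rowTotals}, \code{colTotals}, \code{grandTotal}, \code{units}.
#' @export
crosstabArea <- function(layerA, layerB, namesA = NULL, namesB = NULL) {
  if (!identical(dim(layerA@values), dim(layerB@values)) ||
      !identical(layerA@cellSize, layerB@cellSize) ||
      !identical(layerA@origin, layerB@origin))
    stop("layers are not aligned")
  a <- as.vector(layerA@values); b <- as.vector(layerB@values)
  ok <- !is.na(a) & !is.na(b)
  # declared categories keep their (possibly zero-area) rows and columns
  lev <- function(v, g) if (isCategorical(g)) g@categories else
    sort(unique(v))
  counts <- table(factor(a[ok], levels = lev(a[ok], layerA)),
                  factor(b[ok], levels = lev(b[ok], layerB)))
  cells <- unclass(as.matrix(counts)) * cellAreaHa(layerA)
  if (!is.null(namesA))
    rownames(cells) <- codeName(namesA, as.numeric(rownames(cells)))
  if (!is.null(namesB))
    colnames(cells) <- codeName(namesB, as.numeric(colnames(cells)))
  areaCrossTab(cells)
}

#' Construct an AreaCrossTab from a cell matrix
#'
#' @param cells non-negative matrix of hectares.
#' @return an \code{AreaCrossTab} with margins computed from the cells.
#' @export
areaCrossTab <- function(cells) {
  cells <- as.matrix(cells)
  if (any(cells < 0, na.rm = TRUE)) stop("cell areas must be non-negative")
  structure(list(cells = cells, rowTotals = rowSums(cells),
                 colTotals = colSums(cells), grandTotal = sum(cells),
                 units = "ha"),
            class = "AreaCrossTab")
}

#' @export
print.AreaCrossTab <- function(x, ...) {
  cat(sprintf("AreaCrossTab (%s), grand total %.0f\n", x$units,
              x$grandTotal))
  print(x$cells)
  invisible(x)
}

#' Sum a selection of an AreaCrossTab
#'
#' @param tab an \code{AreaCrossTab}.
#' @param rows,cols row/column names or indices; NULL selects all.
#' @return total hectares of the selection.
#' @export
sumSelect <- function(tab, rows = NULL, cols = NULL) {
  m <- tab$cells
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  sum(m)
}

#' Percentage share, rounded as reported
#'
#' 100 times the numerator sum over the denominator sum, rounded half-up
#' to the reported precision (integer percent by default).
#'
#' @param numerator,denominator numeric vectors (summed) of hectares.
#' @param digits decimal places of the reported percentage.
#' @return the rounded percentage.
#' @examples
#' percentShare(c(9497, 9732), 30173)  # 64
#' @export
percentShare <- function(numerator, denominator, digits = 0) {
  den <- sum(denominator)
  if (den <= 0) stop("denominator must be positive")
  roundHalfUp(100 * sum(numerator) / den, digits)
}

#' Combined commercially redundant area
#'
#' Total flood-driven redundant area: existing redundant oil palm plus
#' unprotected forest predicted to become redundant if converted.
#'
#' @param existingRedundantHa hectares of existing redundant oil palm.
#' @param predictedUnsuitableForestHa hectares of forest predicted
#'   unsuitable.
#' @return their sum in hectares.
#' @export
combinedRedundancy <- function(existingRedundantHa,
                               predictedUnsuitableForestHa) {
  if (existingRedundantHa < 0 || predictedUnsuitableForestHa < 0)
    stop("areas must be non-negative")
  existingRedundantHa + predictedUnsuitableForestHa
}

# md5 registry of the packaged reference tables; filled in by the
# fixture-generation script and verified on every read
fixtureChecksums <- c(
  table1 = "e5356a06f76ad82d715cf0438b6ccdbb",
  table3 = "dcf12af9aa2ee077aa06d7f808b4ba90",
  table4 = "375b797303be63ff10d46ab70840da11",
  table5 = "c8bd9d4d0cd09db568d6bc1011565ff2",
  table6_anchors = "69a271f11006933131e518baed52a7c8",
  constants = "8554af35e2d0b8c6a04afeba7091e6f1"
)

fixturePath <- function(name) {
  f <- system.file("extdata", paste0(name, ".csv"), package = "floodpalm")
  if (f == "") stop("unknown reference table: ", name)
  f
}

#' Packaged regional reference tables
#'
#' Returns the packaged transcriptions of the regional land-cover,
#' land-title and economics tables for the studied floodplain (units: ha,
#' or USD/ha/yr for the NPV anchors). Each file is verified against its
#' md5 checksum before use. Available names:
#' \describe{
#'   \item{table1}{forest systems and types: total / protected /
#'     unprotected hectares.}
#'   \item{table3}{land-title types over the unprotected forest.}
#'   \item{table4}{land-title cross-tabs of forest systems and of modelled
#'     suitability (returned as a list of two \code{AreaCrossTab}s).}
#'   \item{table5}{land-title cross-tab of the oil palm age/productivity
#'     classes (an \code{AreaCrossTab}).}
#'   \item{table6_anchors}{annualized NPV class endpoints at 11\%
#'     discount.}
#'   \item{constants}{region-level scalar areas (study-region extent,
#'     existing redundant oil palm, predicted unsuitable forest).}
#' }
#'
#' @param name one of the table names above.
#' @return a data.frame, \code{AreaCrossTab}, or list of
#'   \code{AreaCrossTab}s depending on the table.
#' @export
tableFixture <- function(name) {
  name <- match.arg(name, names(fixtureChecksums))
  path <- fixturePath(name)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(fixtureChecksums[name])))
    stop(sprintf("reference table '%s' failed its checksum", name))
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  switch(name,
    table4 = {
      split4 <- function(section) {
        s <- d[d$section == section, ]
        m <- as.matrix(s[, c("NT", "CL", "state_demarcated",
                             "state_undemarcated")])
        rownames(m) <- s$class
        areaCrossTab(m)
      }
      list(forestSystems = split4("forest_system"),
           suitability = split4("suitability"))
    },
    table5 = {
      m <- as.matrix(d[, c("NT", "CL", "state_or_undemarcated")])
      rownames(m) <- d$class
      areaCrossTab(m)
    },
    d)
}
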