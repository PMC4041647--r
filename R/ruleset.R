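#' Flood-driven oil-palm suitability decision rules
#'
#' The three decision rules that flag floodplain land as commercially
#' unsuitable (redundant) for oil palm, expressed on the three informative
#' predictors: Euclidean distance to the main river (m), elevation (m ASL)
#' and soil agricultural-suitability class. Evaluated in order, first match
#' wins, and any point matching no rule defaults to \code{full_stand}:
#'
#' \enumerate{
#'   \item within 1,504 m of the river and at or below 22.4 m ASL;
#'   \item beyond 1,504 m, at or below 16 m ASL, on marginal soil
#'     (class 2);
#'   \item beyond 1,947 m, on very suitable soil (class 4), between
#'     9.9 m and 14 m ASL.
#' }
#'
#' All three capture low-lying, inundation-prone land where palm mortality
#' makes cultivation commercially redundant.
#'
#' @return a \code{RuleSet} object (S3): an ordered list of rules plus a
#'   default class.
#' @examples
#' rs <- floodplainRuleset()
#' applyRuleset(rs, distRiver = 1000, elevation = 20, soil = 3)
#' @export
floodplainRuleset <- function() {
  newRuleset(
    rules = list(
      list(class = "redundant", conditions = list(
        list(var = "distRiver", op = "le", value = 1504),
        list(var = "elevation", op = "le", value = 22.4))),
      list(class = "redundant", conditions = list(
        list(var = "distRiver", op = "gt", value = 1504),
        list(var = "elevation", op = "le", value = 16),
        list(var = "soil", op = "in", value = 2))),
      list(class = "redundant", conditions = list(
        list(var = "distRiver", op = "gt", value = 1947),
        list(var = "soil", op = "in", value = 4),
        list(var = "elevation", op = "ge", value = 9.9),
        list(var = "elevation", op = "le", value = 14)))
    ),
    default = "full_stand"
  )
}

#' Construct a RuleSet
#'
#' @param rules ordered list of rules; each rule is a list with a
#'   \code{class} and a list of \code{conditions}, each condition a list
#'   \code{(var, op, value)} with op one of \code{le}, \code{lt},
#'   \code{ge}, \code{gt}, \code{in}.
#' @param default class assigned when no rule matches.
#' @return an object of S3 class \code{RuleSet}.
#' @export
newRuleset <- function(rules, default) {
  structure(list(rules = rules, default = default), class = "RuleSet")
}

#' @export
print.RuleSet <- function(x, ...) {
  cat(sprintf("RuleSet: %d rule(s), default -> %s\n",
              length(x$rules), x$default))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    conds <- vapply(r$conditions, function(cc) {
      op <- switch(cc$op, le = "<=", lt = "<", ge = ">=", gt = ">",
                   "in" = "in")
      paste(cc$var, op, paste(cc$value, collapse = ","))
    }, character(1))
    cat(sprintf("  %d. %s -> %s\n", i, paste(conds, collapse = " & "), r$class))
  }
  invisible(x)
}

evalCondition <- function(cond, env) {
  v <- env[[cond$var]]
  if (is.null(v)) stop(sprintf("missing predictor '%s'", cond$var))
  switch(cond$op,
         le = v <= cond$value,
         lt = v <  cond$value,
         ge = v >= cond$value,
         gt = v >  cond$value,
         "in" = v %in% cond$value,
         stop("unknown condition op: ", cond$op))
}

#' Apply a rule set to predictor vectors
#'
#' Vectorized, first-match-wins evaluation. NA in any predictor a rule
#' inspects yields NA for that point.
#'
#' @param rules a \code{RuleSet}.
#' @param ... named predictor vectors of equal length (e.g.
#'   \code{distRiver}, \code{elevation}, \code{soil}).
#' @return character vector of class labels.
#' @export
applyRuleset <- function(rules, ...) {
  env <- list(...)
  n <- length(env[[1]])
  out <- rep(rules$default, n)
  anyNA <- Reduce(`|`, lapply(env, is.na), rep(FALSE, n))
  assigned <- rep(FALSE, n)
  for (r in rules$rules) {
    hit <- rep(TRUE, n)
    for (cond in r$conditions) {
      h <- evalCondition(cond, env)
      h[is.na(h)] <- FALSE
      hit <- hit & h
    }
    sel <- hit & !assigned
    out[sel] <- r$class
    assigned <- assigned | hit
  }
  out[anyNA] <- NA_character_
  out
}

#' Classify a landscape raster with a rule set
#'
#' Cell-wise application of a suitability \code{RuleSet} to the aligned
#' predictor layers of a [LandscapeStack-class]. Nodata cells propagate to
#' nodata.
#'
#' @param stack a [LandscapeStack-class] (or a named list with RasterGrid
#'   elements \code{distRiver}, \code{elevation}, \code{soil}).
#' @param rules a \code{RuleSet}; defaults to [floodplainRuleset()].
#' @return a categorical [RasterGrid-class] with codes from
#'   [suitabilityCodes] (0 = full_stand, 1 = redundant).
#' @export
classifyRaster <- function(stack, rules = floodplainRuleset()) {
  getLayer <- function(nm) {
    l <- if (is(stack, "LandscapeStack")) slot(stack, nm) else stack[[nm]]
    if (is.null(l)) stop(sprintf("stack is missing layer '%s'", nm))
    l
  }
  dR <- getLayer("distRiver"); el <- getLayer("elevation")
  so <- getLayer("soil")
  lab <- applyRuleset(rules,
                      distRiver = as.vector(dR@values),
                      elevation = as.vector(el@values),
                      soil = as.vector(so@values))
  code <- unname(suitabilityCodes[lab])
  rasterGrid(matrix(code, nrow(dR@values), ncol(dR@values)),
             cellSize = dR@cellSize, origin = dR@origin,
             categories = unname(suitabilityCodes))
}

#' Read or write a RuleSet as JSON
#'
#' Rules are serialized with explicit per-condition operators and values so
#' a ruleset file is self-describing.
#'
#' @param rules a \code{RuleSet}.
#' @param path file path.
#' @return \code{readRuleset} returns a \code{RuleSet}.
#' @export
writeRuleset <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRuleset
#' @export
readRuleset <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(x$rules, function(r) {
    list(class = r$class, conditions = lapply(r$conditions, function(cc)
      list(var = cc$var, op = cc$op, value = unlist(cc$value))))
  })
  newRuleset(rules, default = x$default)
}
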