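#' Default full-stand fresh-fruit-bunch yield curve
#'
#' The 25-year yield curve (t FFB/ha by crop year) for a full stand at 136
#' palms per hectare: zero yield in the two immature years, a monotone ramp
#' to the 30 t peak plateau in years 8-11, then a linear decline to 17 t in
#' year 25. The mean over the 25-year crop life is exactly 21.92 t FFB/ha.
#'
#' @return a \code{YieldCurve}: numeric vector of length 25 with S3 class
#'   \code{"YieldCurve"}.
#' @examples
#' y <- defaultYieldCurve()
#' mean(y)          # 21.92
#' y[8:11]          # 30 30 30 30
#' @export
defaultYieldCurve <- function() {
  y <- c(0, 0, 11.5, 17, 22, 26, 29, rep(30, 4), 30 - 13 * (1:14) / 14)
  yieldCurve(y)
}

#' Construct a YieldCurve
#'
#' @param yields numeric vector of exactly 25 non-negative annual yields
#'   (t FFB/ha, crop years 1-25).
#' @return a \code{YieldCurve}.
#' @export
yieldCurve <- function(yields) {
  yields <- as.numeric(yields)
  if (length(yields) != 25)
    stop("a yield curve spans exactly 25 crop years")
  if (any(!is.finite(yields)) || any(yields < 0))
    stop("yields must be finite and non-negative")
  structure(yields, class = "YieldCurve")
}

#' Scale a yield curve by palm capacity
#'
#' Yield is assumed directly proportional to the fraction of the full
#' 136-SPH planting density actually standing, so every year's yield is
#' multiplied by \code{capacity}.
#'
#' @param curve a \code{YieldCurve}.
#' @param capacity fraction of full palm capacity in [0, 1].
#' @return the scaled \code{YieldCurve}.
#' @export
scaleYield <- function(curve, capacity) {
  if (!is.numeric(capacity) || length(capacity) != 1 ||
      capacity < 0 || capacity > 1)
    stop("capacity must be a single fraction in [0, 1]")
  yieldCurve(as.numeric(curve) * capacity)
}

#' Construct a CostSchedule
#'
#' The three recurrent cost categories of the plantation model: fixed
#' per-hectare general charges and field upkeep, harvesting-and-transport
#' proportional to the tonnage harvested, plus a supplying (replanting)
#' base cost incurred in years 1-2 only and scaled by the missing fraction
#' of palm capacity.
#'
#' @param generalCharges USD/ha/yr, fixed.
#' @param fieldUpkeep USD/ha/yr, fixed.
#' @param harvestTransportRate USD per t FFB harvested.
#' @param supplyingBase USD/ha applied in years 1-2, multiplied by
#'   \code{(1 - capacity)}.
#' @return a \code{CostSchedule} (S3 list).
#' @export
costSchedule <- function(generalCharges, fieldUpkeep, harvestTransportRate,
                         supplyingBase = 100) {
  x <- list(generalCharges = generalCharges, fieldUpkeep = fieldUpkeep,
            harvestTransportRate = harvestTransportRate,
            supplyingBase = supplyingBase)
  if (any(vapply(x, function(v) !is.numeric(v) || v < 0, logical(1))))
    stop("all cost components must be non-negative numbers")
  structure(x, class = "CostSchedule")
}

#' Construct an EconomicScenario
#'
#' @param price USD per t FFB (default 178, the 2011 regional average).
#' @param discountRate annual discount rate as a fraction (default 0.11,
#'   the industry rate; sensitivity set 0.05, 0.08, 0.14).
#' @param capacity fraction of the 136-SPH full planting density in [0, 1].
#' @param horizon crop life in years (fixed at 25).
#' @return an \code{EconomicScenario} (S3 list).
#' @export
economicScenario <- function(price = 178, discountRate = 0.11,
                             capacity = 1, horizon = 25) {
  if (price <= 0) stop("price must be positive")
  if (capacity < 0 || capacity > 1) stop("capacity must lie in [0, 1]")
  if (discountRate <= -1) stop("discount rate must exceed -1")
  if (horizon != 25) stop("the crop-life horizon is fixed at 25 years")
  structure(list(price = price, discountRate = discountRate,
                 capacity = capacity, horizon = horizon),
            class = "EconomicScenario")
}

#' Annual net cash flows of a plantation scenario
#'
#' For each crop year t, with the capacity-scaled yield y(t):
#' \deqn{net(t) = price \cdot y(t) - general - upkeep -
#'   harvestRate \cdot y(t) - supplying(t)}
#' where \eqn{supplying(t) = supplyingBase \cdot (1 - capacity)} in years
#' 1-2 and 0 afterwards. The curve passed in should already be scaled to
#' the scenario's capacity (see [scaleYield()]).
#'
#' @param curve a capacity-scaled \code{YieldCurve}.
#' @param costs a \code{CostSchedule}.
#' @param scenario an \code{EconomicScenario}.
#' @return numeric vector of 25 net flows (USD/ha), class
#'   \code{"CashFlowSeries"}.
#' @export
cashFlows <- function(curve, costs, scenario) {
  y <- as.numeric(curve)
  supplying <- c(rep(costs$supplyingBase * (1 - scenario$capacity), 2),
                 rep(0, 23))
  net <- scenario$price * y - costs$generalCharges - costs$fieldUpkeep -
    costs$harvestTransportRate * y - supplying
  structure(net, class = "CashFlowSeries")
}

#' Net present value of a 25-year cash-flow series
#'
#' \deqn{NPV = \sum_{t=1}^{25} net(t) / (1 + rate)^t}
#' with the annualized value defined as NPV / 25.
#'
#' @param series a \code{CashFlowSeries} (or numeric vector of length 25).
#' @param rate annual discount rate (fraction, > -1).
#' @return list with \code{npvTotal} (USD/ha over 25 years) and
#'   \code{npvAnnualized} (USD/ha/yr).
#' @examples
#' npv(c(100, rep(0, 24)), 0.11)$npvTotal  # 90.09
#' @export
npv <- function(series, rate) {
  if (rate <= -1) stop("discount rate must exceed -1")
  s <- as.numeric(series)
  if (length(s) != 25) stop("cash-flow series must span 25 years")
  total <- sum(s / (1 + rate)^(1:25))
  list(npvTotal = total, npvAnnualized = total / 25)
}

#' Annualized NPV of a plantation at a given palm capacity
#'
#' End-to-end evaluation: scales the full-stand yield curve to the
#' capacity, builds the net cash flows under the cost schedule and price,
#' discounts at the given rate and annualizes (NPV / 25).
#'
#' @param capacity palm-capacity fraction in [0, 1].
#' @param curve the full-stand \code{YieldCurve}.
#' @param costs a \code{CostSchedule}.
#' @param price USD per t FFB.
#' @param rate annual discount rate.
#' @return annualized NPV, USD/ha/yr.
#' @export
annualizedNPV <- function(capacity, curve, costs, price = 178,
                          rate = 0.11) {
  sc <- economicScenario(price = price, discountRate = rate,
                         capacity = capacity)
  npv(cashFlows(scaleYield(curve, capacity), costs, sc),
      rate)$npvAnnualized
}

#' Calibrate the cost schedule against two NPV anchors
#'
#' The cost magnitudes behind the plantation model are not printed; instead
#' the two identifiable cost parameters — the total fixed annual cost
#' (split between general charges and field upkeep) and the
#' yield-proportional harvesting-and-transport rate — are solved in closed
#' form so the model reproduces two annualized-NPV anchors at given
#' capacities. The defaults are the full-stand class bounds at 11\%
#' discount: capacity 1.00 at $637/ha/yr and capacity 0.76 at $413/ha/yr.
#'
#' Because both revenue and harvest cost scale linearly with capacity, and
#' supplying scales with (1 - capacity), annualized NPV is affine in
#' capacity; two anchors pin the line down completely and the supplying
#' base (small, held at its default) cancels out of every prediction on
#' the line.
#'
#' @param anchorLow,anchorHigh numeric \code{c(capacity, annualizedNPV)}
#'   pairs with distinct capacities.
#' @param curve the full-stand \code{YieldCurve}.
#' @param price USD per t FFB.
#' @param rate discount rate used by the anchors.
#' @param supplyingBase supplying base cost (USD/ha, years 1-2).
#' @param fixedSplit fraction of the fixed cost assigned to general
#'   charges (remainder is field upkeep); only their sum is identified.
#' @return a calibrated \code{CostSchedule} reproducing both anchors to
#'   within 0.5 USD/ha/yr.
#' @export
calibrateCosts <- function(anchorLow = c(0.76, 413),
                           anchorHigh = c(1.00, 637),
                           curve = defaultYieldCurve(), price = 178,
                           rate = 0.11, supplyingBase = 100,
                           fixedSplit = 0.4) {
  cLo <- anchorLow[1]; vLo <- anchorLow[2]
  cHi <- anchorHigh[1]; vHi <- anchorHigh[2]
  if (cLo == cHi) stop("anchor capacities must be distinct")
  t <- 1:25
  disc <- (1 + rate)^-t
  Yd <- sum(as.numeric(curve) * disc)      # discounted full-stand tonnage
  A <- sum(disc)                           # 25-year annuity factor
  D <- sum(disc[1:2])                      # years-1..2 discount weight
  # annualized NPV(c) = [c*(price-h)*Yd - K*A - (1-c)*S*D] / 25
  margin <- (25 * (vHi - vLo) / (cHi - cLo) - supplyingBase * D) / Yd
  h <- price - margin                      # harvest & transport per t
  K <- (cHi * margin * Yd - (1 - cHi) * supplyingBase * D - 25 * vHi) / A
  if (h < 0 || K < 0)
    stop("anchors are infeasible: calibration would need negative costs")
  costSchedule(generalCharges = fixedSplit * K,
               fieldUpkeep = (1 - fixedSplit) * K,
               harvestTransportRate = h, supplyingBase = supplyingBase)
}

#' Discount-rate sensitivity table of annualized NPV
#'
#' One annualized NPV per (capacity, rate) combination, mirroring the
#' published sensitivity layout: rows are the capacity endpoints of the
#' productivity classes, columns the discount rates.
#'
#' @param curve the full-stand \code{YieldCurve}.
#' @param costs a \code{CostSchedule}.
#' @param capacities numeric vector of capacities in [0, 1].
#' @param rates numeric vector of discount rates.
#' @param price USD per t FFB.
#' @return data.frame with a \code{capacity} column and one column per
#'   rate (named \code{rate_<pct>}), values in USD/ha/yr.
#' @export
sensitivityTable <- function(curve = defaultYieldCurve(),
                             costs = calibrateCosts(),
                             capacities = c(0, 0.25, 0.26, 0.50, 0.51,
                                            0.75, 0.76, 1.00),
                             rates = c(0.05, 0.08, 0.11, 0.14),
                             price = 178) {
  stopifnot(length(capacities) > 0, length(rates) > 0)
  out <- data.frame(capacity = capacities)
  for (r in rates)
    out[[sprintf("rate_%g", 100 * r)]] <-
      vapply(capacities, annualizedNPV, numeric(1), curve = curve,
             costs = costs, price = price, rate = r)
  out
}

#' Break-even palm capacity
#'
#' The capacity at which annualized NPV crosses zero, found by bisection to
#' within 0.01 USD/ha/yr. Requires NPV(0) < 0 < NPV(1).
#'
#' @inheritParams sensitivityTable
#' @param rate discount rate.
#' @return the break-even capacity fraction.
#' @export
breakevenCapacity <- function(curve = defaultYieldCurve(),
                              costs = calibrateCosts(), rate = 0.11,
                              price = 178) {
  f <- function(cc) annualizedNPV(cc, curve, costs, price, rate)
  lo <- 0; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  if (!(flo < 0 && fhi > 0))
    stop("no sign change: NPV(0) must be negative and NPV(1) positive")
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 0.01) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
}

#' Palm productivity classes and their capacity bounds
#'
#' The four modelled productivity classes with their palm-capacity ranges
#' (fractions of the 136-SPH full density): full stand (0.76, 1.00],
#' underproductive at 75\% (0.51, 0.75], at 50\% (0.26, 0.50], and at or
#' below 25\% [0, 0.25]. Class endpoints use the nominal percentages.
#'
#' @return data.frame with columns class, capacityLow, capacityHigh.
#' @export
productivityClasses <- function() {
  data.frame(
    class = c("full_stand", "up75", "up50", "up25"),
    capacityLow = c(0.76, 0.51, 0.26, 0),
    capacityHigh = c(1.00, 0.75, 0.50, 0.25)
  )
}

#' Annualized NPV table for the productivity-class endpoints
#'
#' Evaluates the calibrated model at the low and high capacity endpoint of
#' each productivity class at one discount rate — the per-class NPV range
#' table of the analysis.
#'
#' @inheritParams sensitivityTable
#' @param rate discount rate.
#' @return data.frame with class, capacity endpoints and their annualized
#'   NPVs (USD/ha/yr).
#' @export
classNPVTable <- function(curve = defaultYieldCurve(),
                          costs = calibrateCosts(), rate = 0.11,
                          price = 178) {
  pc <- productivityClasses()
  pc$npvLow <- vapply(pc$capacityLow, annualizedNPV, numeric(1),
                      curve = curve, costs = costs, price = price,
                      rate = rate)
  pc$npvHigh <- vapply(pc$capacityHigh, annualizedNPV, numeric(1),
                       curve = curve, costs = costs, price = price,
                       rate = rate)
  pc
}
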