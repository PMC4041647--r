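---
title: "Methods: floodplain oil-palm suitability and economics"
author: "floodpalm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: floodplain oil-palm suitability and economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodpalm)
```

## The problem

Oil palm is flood-intolerant: root saturation kills palms within weeks,
so in riverine floodplains the low-lying land nearest the channel —
often the last unprotected forest — can be converted to plantations that
never pay back. `floodpalm` packages the three quantitative pieces needed
to analyse this at the landscape scale: a capacity-scaled discounted
cash-flow model of a 25-year oil-palm rotation, flood-driven land
suitability classification (fixed decision rules, and CART induction
that re-learns such rules from training points), and the accounting
machinery (confusion matrices, kappa, hectare cross-tabulations) that
turns maps into headline numbers.

## The cash-flow model

One hectare is modelled over a 25-year crop life. Revenue is the sale of
fresh fruit bunches (FFB) at a constant price `p` (default US$178/t, a
2011 east-Sabah average). Production follows a full-stand yield curve
`y(t)` scaled by *palm capacity* `c`, the standing fraction of the full
136 stems-per-hectare planting density; yield is assumed directly
proportional to capacity. The default curve (`defaultYieldCurve()`) has
zero yield in the two immature years, a monotone ramp to a 30 t FFB/ha
plateau in years 8–11, and a linear decline to 17 t in year 25; its
25-year mean is exactly 21.92 t. Within these constraints the ramp values
(11.5, 17, 22, 26, 29 t in years 3–7) are the package's choice, fixed so
the mean is met exactly.

Costs take the minimal structure consistent with the three standard
recurrent categories:

* general charges `G` and field upkeep `F` — fixed, USD/ha/yr;
* harvesting and transport `h` — USD per tonne actually harvested, the
  only yield-proportional cost;
* supplying (replanting of dead palms) — a base `S` (USD/ha) charged in
  years 1–2 only and scaled by the missing capacity `(1 − c)`.

Net flow is `net(t) = (p − h)·y(t)·c − G − F − S·(1 − c)·1[t ≤ 2]`, and
`npv()` discounts at rate `r` (default 11%/yr, the industry rate;
sensitivity set 5, 8, 14%). Results are annualized as NPV/25: the
magnitudes of per-class results are only consistent with per-year values,
and the package states the division explicitly since "per 25 years" and
"per year" labels are easily conflated in this literature.

### Calibration

Absolute cost magnitudes are rarely published. `calibrateCosts()`
therefore solves for the two identifiable parameters — the fixed total
`K = G + F` (split 40/60 by convention; only the sum is identified) and
the harvest rate `h` — in closed form from two annualized-NPV anchors,
by default the full-stand class bounds at 11%: capacity 0.76 at $413 and
1.00 at $637/ha/yr. Writing `Y_d` for the discounted full-stand tonnage,
`A` for the 25-year annuity factor and `D` for the years-1–2 discount
weight:

```
(p − h)·Y_d = 25·(v_hi − v_lo)/(c_hi − c_lo) − S·D
K·A         = c_hi·(p − h)·Y_d − (1 − c_hi)·S·D − 25·v_hi
```

Anchors that would force `h < 0` or `K < 0` raise a calibration error.
Because revenue and harvest cost are linear in `c` and supplying is
linear in `(1 − c)`, annualized NPV is *exactly affine* in capacity, and
the supplying base cancels out of every prediction on the two-anchor
line — so `S` (default $100/ha, deliberately small) only matters if one
departs from the linear supplying assumption. The class-endpoint NPVs and
the break-even capacity (bisection on the annualized NPV to within
$0.01/ha/yr) all follow from the calibrated line.

## Suitability classification

`floodplainRuleset()` encodes the three flood-driven rules on the
informative predictors (Euclidean distance to the main river, elevation,
and a four-class agricultural soil-suitability layer; aspect and slope
carry no signal): land is redundant when (1) within 1,504 m of the river
at ≤22.4 m ASL; (2) beyond 1,504 m, at ≤16 m ASL on marginal soil; or
(3) beyond 1,947 m, on very suitable soil, between 9.9 and 14 m ASL.
Rules are evaluated in order, first match wins, default `full_stand`;
since all rules map to the same class, order affects explanation only.
Boundary semantics are `≤ threshold` throughout.

### CART

`growTree()` is a from-scratch classification tree: exhaustive search
over midpoints between consecutive sorted distinct values, maximising
the weighted Gini impurity decrease, ties broken by variable declaration
order then by the lower threshold, with `x ≤ threshold` going left. The
ordinal soil code is split as numeric; `extractRules()` reports soil
conditions back as matched class sets (a split pair `1.5 < soil ≤ 2.5`
reads out as "soil in {2}"). Defaults are `minLeaf = 5` and
`maxDepth = 10`: a depth of 6 is enough for the printed three-rule tree
itself, but expressing the *complete* three-rule partition as one tree
needs up to depth 8 on the soil branch (distance, two elevation cuts,
three soil cuts, a second distance cut and two more elevation cuts), so
the default leaves headroom while still bounding noise trees.

`pruneTreeCV()` performs cost-complexity (weakest-link) pruning: the
critical complexity sequence is computed from the full tree, each
inter-critical interval is represented by the geometric mean of its ends,
and the misclassification rate of each representative is estimated by
stratified, seeded 10-fold cross-validation in which the tree is re-grown
on every training fold. The complexity is selected by the
one-standard-error rule — the most heavily pruned tree whose CV error is
within one binomial SE of the minimum. Whether to use the 1-SE rule is
genuinely open in this setting; it is declared here, chosen for
parsimony. A consequence worth knowing: on pure-noise labels every
complexity has the same expected CV error, so the empirical minimum is
noise and the 1-SE band does not always reach back to the root — the
pruned tree collapses to a single leaf in most but not all replicates
(the reference `rpart` implementation behaves the same way under cp = 0
growth). Signal recovery is unaffected: on rule-labelled samples with 5%
label noise the pruned tree's held-out accuracy against the generating
rules exceeds 0.95 in every tested seed.

## The synthetic landscape generator

`generateLandscape()` emulates the statistical structure the analysis
assumes, at 1-ha cells (100 m, the resolution of the predictor stack):

* a meandering channel (sinusoidal centreline, amplitude and sinuosity
  parameters), 8-connected, one cell wide;
* exact cell-centre Euclidean distance to the channel (`distanceToRiver`,
  which matches a brute-force minimum exactly — it *is* the exact
  minimum, computed in chunks);
* elevation `elevBase + elevRange·d/(d + floodScale) + noise`: a
  saturating ramp away from the channel plus box-smoothed Gaussian noise
  (sd `noiseSd`, default 1.5 m), non-decreasing in expectation with
  distance. `floodScale` (default 1,500 m) is the flood-extent control:
  larger values keep low-lying land extending further from the channel;
* patchy soils: a box-smoothed Gaussian random field cut at its quartiles
  into classes 1–4. The patch size (`soilPatchSize`, default 5 cells) is
  a free choice — no empirical autocorrelation scale is available for the
  emulated layer;
* a productivity layer labelled by the suitability rules, with a fraction
  `labelNoise` of labels flipped (Bernoulli, per cell);
* a land-title tessellation of non-overlapping rectangular parcels:
  Native Title smallholdings strictly under 40 ha, large Country Land
  leases, demarcated State land, remainder undemarcated;
* aspect and slope layers that are pure noise by construction.

All randomness flows from one integer seed through a private RNG stream;
identical `(shape, params, seed)` give bit-identical stacks, and the
user's RNG state is untouched.

`generateTrainingSamples()` draws point training data on regular design
grids (distance in 20 m steps over 0–5,000 m; elevation in 0.25 m steps
over 0–40 m; soils 1–4), stratified over the partition cells the rule
thresholds induce, with each cell's corner grid values pinned before the
random fill. The pinning guarantees every decision boundary is flanked
at adjacent grid values on both sides, so a recovered split threshold —
which CART places at a data midpoint — sits within one grid step of the
generating threshold; uniform sampling leaves the small rule-3 region too
sparse for that guarantee.

What the generator does *not* emulate: real flood frequency or hydrology
(inundation risk enters only through the elevation/distance structure
the rules read), spatially correlated label noise, curvilinear parcel
boundaries, and any correlation between soil and elevation. Passing
tests therefore demonstrate the correctness of the algorithms under the
assumed structure, not the realism of any particular floodplain.

## Accuracy and accounting

`confusionMatrix()` cross-tabulates reference (rows) against predicted
(columns) labels; orientation is a convention only, as overall accuracy
(trace/total) and Cohen's kappa `(p_o − p_e)/(1 − p_e)` are
orientation-invariant. Degenerate margins with `p_e = 1` return kappa 1
under perfect agreement and are an error otherwise. `kappaQuality()`
reports verbal grades under two published scales as metadata strings.

`crosstabArea()` converts aligned categorical rasters into hectare
tables; nodata in either layer removes the cell from all totals, declared
categories keep their (possibly zero) rows, and the grand total equals
cell count × cell area exactly. Percentages are rounded *half-up* to the
printed precision (`roundHalfUp`), the convention that reproduces every
checkable reported percentage; base R's round-half-even does not.

The packaged reference tables (`tableFixture()`) are checksummed CSV
transcriptions. Their printed grand totals disagree with their own cell
sums by up to 2 ha (source rounding); the package stores the printed
cells, recomputes margins from cells — conservation is exact by
construction — and treats the printed totals as annotations with a ±2 ha
slack.

## Problem sizes and tolerances

The test suite works at deliberately modest sizes: landscapes of
25×30–100×100 cells, training sets of 800–5,000 points, 10-fold CV over
10–20 seeds; the full suite runs in well under a minute. Economics are
exact closed forms (equalities tested at machine precision or $0.5/ha/yr
for the calibration anchors); distance transforms are compared exactly
against a double-loop oracle; threshold recovery is asserted to one
design-grid step (20 m / 0.25 m); noisy-CART held-out accuracy at ≥0.95;
the label-noise realisation at ±0.01 on 10,000 cells.

## Known limitations

* The economics are per-hectare and recurrent-cost only: no new-planting
  capital, no mill costs, no crude-palm-oil conversion, no labour or
  harvestability constraints — FFB revenue is the unit of account.
* Capacity endpoints use nominal class percentages (e.g. 0.76), not
  rounded stems-per-hectare ratios.
* The suitability rules are static thresholds; no hydrological
  simulation stands behind them.
* CART equivalence with other implementations is at the level of
  recovered thresholds and accuracy, not tree topology.
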