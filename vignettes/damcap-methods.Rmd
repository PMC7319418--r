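---
title: "Methods behind the dam capacity model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the dam capacity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damcap)
```

This vignette documents the modelling choices in `damcap`: what each stage
computes, why the defaults look the way they do, and where the synthetic
catchment generator is (and is not) a faithful stand-in for real data.

## Beaver forage index

The forage index scores every 5 m cell from 0 (unsuitable) to 5 (preferred
forage). Scores come from up to four landcover sources, each mapped to the
0–5 scale by the editable YAML table in
`system.file("extdata", "bfi_suitability.yaml", package = "damcap")`:

* detailed vector landcover (`os_vector`) — broadleaved and mixed woodland,
  shrub and orchards score 5; conifer and mixed shrub 3; reeds 2; rough
  grassland, heath and marsh 1; water, bare ground and built surfaces 0;
* a categorical landcover raster (`lcm_raster`) with an analogous ranking;
* percent tree cover (`tcd_percent`), banded 1–3% → 1, 4–10% → 2,
  11–50% → 3, 51–100% → 4 — tree cover alone never proves *preferred*
  broadleaf forage, hence the cap at 4;
* mapped woody linear features (`wlff_lines`), scored 4 along a one-cell
  swath.

Sources composite by *priority then maximum*: the detailed vector layer wins
where present; elsewhere the remaining sources take the cell-wise maximum, so
partial evidence of woody vegetation is never diluted by an uninformative
layer. Cells with no data in any source score 0. `classify_bfi_category()`
bins the index at 1, 2, 3 and 4 into unsuitable/low/medium/high/preferred.

## Reach network

`segment_network()` splits mapped channels into working reaches: any feature
of 200 m or more is cut into `ceiling(length / 200)` equal parts (so reaches
stay under 200 m and a 200 m feature yields two 100 m reaches). Bankfull
width per reach is the channel-polygon area within a 20 m reach buffer,
evaluated on a 1 m lattice, divided by reach length; widths floor at 0.5 m
and implausibly large values are flagged.

Reach forage is extracted in two swaths — streamside (10 m beyond the bank)
and riparian (40 m) — offset by the half-width so wide channels do not
swallow their own banks, and summarised as the mean BFI of sampled cells.

## Terrain

The tooling is self-contained: streams are burned 30 m into the DTM along
the mapped network, depressions are removed with a priority-flood fill
(epsilon 1e-6 to keep drainage directed), and D8 directions give flow
accumulation in topological order. Contributing area per reach is the
maximum accumulation along it, in km².

Strahler order needs care. Orders computed on the raster stream network are
systematically one higher than orders on the mapped vector network, because
the raster stream continues upslope of every mapped channel head into
unmapped headwater flow paths. `strahler_with_correction()` therefore (a)
computes raw raster orders, (b) decrements orders above 1, and (c) discards
residual first-order cells that do not coincide with the mapped network.

Two details make this robust across grid resolutions:

* **Head-path pruning.** D8 routing also manufactures spurious channels
  where hillslope flow converges along the bisectors of concave junction
  angles. These artifacts join the network *mid-channel*, whereas genuine
  headwater paths enter *through a channel head*, so the raster stream is
  pruned to the rasterised network plus cells whose flow path first meets it
  at a head. Channel heads are degree-1 feature endpoints that do not lie on
  another feature's line (which excludes tributary mouths); the outlet is the
  endpoint with the largest accumulation.
* **Per-head thresholds.** Which retained cells count as "stream" is decided
  per head: a cell on a head's drainage path qualifies if its accumulation
  reaches 25% of the accumulation at that head. An absolute or global
  threshold fails here, because hillslope laterals and genuine headwater
  branches both scale with the head's own catchment, not with the grid.

Reach order is the maximum corrected cell order sampled along the reach
*interior* (20–80% of its length), which avoids junction cells shared with
neighbouring reaches. The test suite checks the whole chain against an
independent vector-network Strahler oracle on random catchments at 96–512
cells a side.

## Hydrology

`flow_exceedance()` computes Q2 and Q80 from daily gauge records as type-7
quantiles at probability `1 - p/100`; records must span at least 30 days and
warn under a year (seasonality makes shorter records unrepresentative).
Rating curves `Q = a·A^b` are fitted by Levenberg–Marquardt nonlinear least
squares, started from the log–log linear fit; the power-law form is standard
for discharge–area scaling and recovers noiseless curves to machine
precision. Stream power is `Ω = ρ g Q S` with ρg = 9800 N/m³.

## Fuzzy capacity model

Both inference stages are Mamdani systems with trapezoidal membership
functions, `min` implication, `max` aggregation and centroid defuzzification
on a 0.01 grid over [0, 30] dams/km (configs in
`fis_vegetation.yaml`/`fis_combined.yaml`). The vegetation stage crosses
streamside and riparian forage (25 rules, consequent index ≈ 0.6·streamside
+ 0.4·riparian — streamside material matters more for construction). The
combined stage (180 rules) discounts the vegetation capacity: slopes a
beaver *cannot build on* (≥ 20–25%) zero it; *probably can* slopes cost two
categories; high-flow power penalises towards breach (one category) or
blowout (two); low-flow power towards breach or dam oblivion. An input that
fires zero rules raises an error rather than returning a silent 0. Hard
constraints then zero capacity where width exceeds 25 m, drainage area
exceeds 250 km² or Strahler order exceeds 5, and damp fifth-order reaches by
0.9.

## Validation and dam counts

Activity per habitat category is a Binomial likelihood with a uniform
Beta(1, 1) prior, so posteriors are Beta(k+1, n−k+1); the reported point
estimate is the MAP `k/n` with equal-tailed 95% intervals (an HPD option
exists for skewed small-sample posteriors). Category contrasts are
Monte-Carlo ratios of independent Beta draws (≥ 1e5), summarised by the KDE
mode on the log scale (back-transformed with the 1/r Jacobian) and 2.5/97.5%
quantiles; ratios against categories with zero successes are flagged
unbounded rather than reported as numbers.

Observed dam counts are over-dispersed and zero-heavy, so model choice is
explicit: a Cameron–Trivedi dispersion test, then Poisson/NB/ZIP/ZINB
compared by AIC. The ZINB likelihood is maximised directly (BFGS on
`(β₀, β₁, γ₀, γ₁, log θ)` with a log-sum-exp zero term; Wald errors from the
numerical Hessian) and is verified in the tests to match an independent
`glmmTMB` fit to 4 decimal places. Expected dams per reach are
`(1 − π)·μ`; catchment totals carry case-bootstrap percentile intervals
(aborting if more than 10% of refits fail), and percentile-subset
cross-validation pools held-out predictions with a zero-intercept slope
`Σ(p·o)/Σ(p²)` that should sit near 1.

## The synthetic generator, honestly

`catchment_scenario()` exists so the whole pipeline is testable and
reproducible offline. It produces a sloped valley with a main stem and
tributaries, hidden headwater arms above each channel head (so the raster
stream genuinely extends past the mapped heads, as with real DTMs), blockwise
landcover honouring requested mosaic fractions near and away from the
network, power-law gauge flows with lognormal noise, and survey observations
drawn from a known occupancy/ZINB truth (stored as an attribute for
checking recovery).

Its limits: landcover has no spatial autocorrelation beyond 30 m blocks,
channels have fixed synthetic widths, flows at different gauges share one
rating law, and the default mosaic is deliberately forage-rich, so synthetic
catchments skew towards the upper capacity categories. Treat generated
outputs as a correctness harness, not as ecology.

## A compact run

```{r example, eval = FALSE}
scn <- catchment_scenario(grid_shape = c(128, 128), n_tributaries = 3,
                          seed = 7)
res <- run_pipeline(scn, simulate = TRUE, bootstrap_reps = 50)
res$summary
```
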