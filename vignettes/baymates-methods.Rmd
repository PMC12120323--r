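---
title: "Methods: residency, seasonality, space use and co-occurrence from acoustic detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residency, seasonality, space use and co-occurrence from acoustic detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baymates)
library(dplyr)
```

This vignette documents the models and procedures implemented in
`baymates`, the conventions and tunable parameters behind them, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want to know about.

## Input model and inclusion filters

The package consumes three tables: a detection log (`timestamp`,
`transmitter_id`, `receiver_id`), receiver metadata (position, depth,
marine/estuary zone, deployment interval) and tag metadata (species, life
stage, length, tagging date and region, battery expiry, optional recapture
and last-outside-bay detection dates). All timestamps are converted to one
configurable analysis timezone — the default is UTC+02:00, South African
Standard Time — and a *detection day* is a calendar date in that zone
(midnight to midnight, not a rolling 24-h window), because the detection
indices are ratios of day counts.

`filter_dataset()` applies the standard inclusion rules in a fixed order:
estuary-zone receivers and their detections go first (the analyses concern
marine use of the bay), detections from unknown transmitters are dropped
with a logged count (untagged animals and false detections are a fact of
field data, not an error), detections outside an individual's monitoring
window are removed, and finally individuals detected on fewer than
`min_days = 10` distinct days are excluded, with per-individual reason
codes. "Fewer than 10" is read literally: exactly 10 days is retained.
Filtering is idempotent, and the exclusion log partitions the excluded set
— both are asserted by tests.

The monitoring window runs from the tagging date to the earliest of study
end, recapture, battery expiry, or last known detection outside the bay
(`monitoring_end()`). Day spans are inclusive of both endpoints by default
(`end - start + 1`); the exclusive convention is available via
`detection_indices(inclusive = FALSE)` and differs by at most one day. We
do not adjust denominators for receiver downtime: array gaps are treated as
monitoring time, which makes the indices conservative.

Region labels (west/central/east) derive from longitude with a half-open
breakpoint convention. No standard breakpoint values exist, so they are an
explicit argument with defaults that split the array's longitudinal extent
into thirds.

## Detection indices and group comparisons

For each retained individual, `DI_total` divides distinct detection days by
total days monitored and `DI_bay` divides the same numerator by days at
liberty up to the last in-bay detection. Since the second denominator never
exceeds the first, `DI_total <= DI_bay` always — a property test, not an
assumption. Monthly detection tables carry the number of detection days per
calendar month together with the month's calendar length, which becomes the
offset of the seasonal model.

`compare_groups()` routes two groups to a Mann–Whitney U test (normal
approximation, tie-corrected) and three or more to a tie-corrected
Kruskal–Wallis test, both delegated to the standard R implementations.
Dunn's post hoc test is implemented in the package (pairwise z on mean
ranks with tie-corrected variance, two-sided p, Benjamini–Hochberg
adjustment across pairs) because no suitable implementation is available as
a dependency. Degenerate all-tied inputs return statistic 0 with p = 1
rather than failing, so automated pipelines survive pathological strata.

## The cyclic-seasonal detection model

The response is the per-individual count of detection days in a month,
`quasi-Poisson` with a log link:

```
log E(count) = alpha_species + f_species(month) + b_individual + log(days in month)
```

Design choices, in the order they matter:

- **Basis.** `f_species` uses a periodic cubic B-spline basis over month
  positions `[1, 13)` with `k = 12` equally spaced knots, built by folding
  the wrap-around columns of an extended B-spline design. Rows sum to one
  and the curve is C² across the December–January join (both verified
  numerically in tests). Because the basis rows sum to one, each smooth is
  confounded with its species intercept; a sum-to-zero reparameterization
  (coefficients orthogonal to the constant) removes the confound, and a
  cyclic second-difference penalty supplies the smoothness prior.
- **Random intercepts.** Individual effects enter as a ridge-penalized
  indicator block — the standard equivalence between an i.i.d. Gaussian
  random intercept and an L2 penalty. This keeps the whole fit inside one
  penalized IRLS loop.
- **Smoothing selection.** Two penalty weights (smooth, ridge) are chosen
  by grid-search GCV on the deviance, `n·D / (n - edf)²`, over log-spaced
  grids (`10^-3…10^6` for the smooth, `10^-1…10^3` for the ridge). Grid
  search is deliberate: it is reproducible, monotone in cost, and adequate
  at the scale of monthly tables; smoothing parameters can also be fixed.
- **Dispersion and inference.** The quasi-Poisson scale is Pearson χ²
  over residual degrees of freedom (`n - edf`). Per-species smooth terms
  are tested with an approximate quasi-F drop test: the model is refit with
  that species' smooth penalized to flatness and the scaled deviance
  difference is referred to `F(edf_drop, n - edf)`. This is approximate by
  construction (penalized estimation, estimated scale) and is labelled as
  such; exact agreement with `mgcv`'s EDF/F reporting is a non-goal, though
  a test checks that fitted curves correlate strongly with an `mgcv`
  reference fit on the same data.
- **Limits.** With the smoothing penalty driven to infinity the curve goes
  flat and the model collapses to species intercepts with offset, whose
  MLE is the closed-form total-days ratio — both verified exactly. A
  species with no detections is driven to probability zero with a warning
  rather than an error.

Predicted monthly values are per-day detection probabilities: the
exponentiated linear predictor at unit offset, clipped to `[0, 1]`, with
delta-method standard errors.

## Movement networks and the PERMANOVA

Movement edges are consecutive-detection transitions: scanning each
individual's detections chronologically, a pair of *different* receivers
within 24 h adds one to that unordered pair's weight. The alternative
reading of a "24-h period" — calendar-day co-visitation — is available via
`rule = "calendar"`, and a directed variant via `directed = TRUE`; the
consecutive undirected form is the default because it matches how
movement-network telemetry studies draw their figures. Node and edge
densities use the *deployed array* as the denominator (all receivers, all
unordered pairs), so densities are comparable across individuals
regardless of which receivers each animal happened to visit.

`permanova()` is implemented from first principles. Squared Euclidean
distances between per-receiver detection-proportion profiles are converted
to the Gower-centered inner-product matrix `G`; each term's sequential
(Type I) sum of squares is `tr(H_t G)` for the increment `H_t` between
successive cumulative hat matrices; pseudo-F is the usual ratio of mean
squares; and p-values come from free permutation of observations with
`p = (1 + #{F* >= F}) / (1 + n_perm)`. Ties are counted with a small
relative tolerance so permutations that merely reproduce the observed
grouping register as ties. Rank-deficient designs (empty interaction
cells, unavoidable in unbalanced field cohorts) lose their aliased columns
with a warning and report realized degrees of freedom, preserving the
identities `sum(df) = N - 1` and `sum(R²) = 1` that every fit must satisfy.
When an explicit permutation set is supplied (e.g. an exhaustive
enumeration at tiny n), the p-value is the exact fraction of that reference
set at or above the observed statistic. The test suite checks equality
with exhaustive enumeration at n = 6, equality of the one-dimensional
two-group pseudo-F with the classical ANOVA F, agreement of df/SS/F/R²
with `vegan::adonis2` (used strictly as a cross-check), and type-I error
calibration under the null.

## Co-occurrence networks, SRI and assortment

Sampling periods are fixed clock-aligned hour bins — not sliding windows —
because they are deterministic and match the plain reading of "detected at
the same receiver within an hour". A grouping event is one (bin, receiver)
set of individuals; an individual seen at two receivers in one bin belongs
to two groups, and for a dyad such a bin counts once as "both observed,
not together" unless they also share a receiver that bin. The simple-ratio
denominator is the number of bins in which at least one member of the dyad
was observed anywhere in the array.

The weighted categorical assortativity builds the mixing matrix from edge
weights (both directions counted), and the node-permutation test shuffles
trait labels over nodes while holding the weighted edge structure fixed.
The default p-value is one-tailed against positive assortment — the
alternative of ecological interest here — with a two-sided option;
the `+1` correction is applied in both numerator and denominator so p is
never zero. Scale invariance (doubling all weights changes nothing) and
label-name invariance are asserted by tests, as is exact agreement with an
independently coded oracle and, for binary weights, with `igraph`'s
nominal assortativity. Individuals with no detections in the analysis
period are not part of the network.

## The synthetic-data generator

`sim_scenario()` fixes the study conditions; `simulate_detections()` draws
from them reproducibly. For each individual and each day of its monitoring
window, presence is Bernoulli with probability
`clamp(base · (1 + A · cos(2π(month - peak)/12)), 0, 1)`; present days draw
a receiver (region by species weight, uniform within region) and a base
hour; with probability `assortment_strength` the individual instead adopts
the receiver and base hour of a randomly chosen present conspecific's own
independent draw, which manufactures same-hour same-receiver co-detections
without a movement model; and each present day emits 1–20 pings across at
most four consecutive hours, the first ping anchored in the base hour so a
co-assigned pair is guaranteed at least one shared hour bin. Ground truth
(day sets, peak months, the co-assignment log) is returned alongside the
emitted tables and is recounted exactly from the log in tests.

Defaults mirror a decade-scale multi-species bay study: a 59-receiver
marine array split 20/20/19 across regions, a cohort of four species
(two estuary-tagged teleosts, two coastally tagged sharks) with
Table-style stratum sizes, daily presence base rates of the order of
published detection indices (0.15–0.39), seasonal peaks in austral summer
(ragged-tooth shark), late winter/spring (white shark) and winter
(leervis) with no seasonal signal for dusky kob, a three-year span, and
`assortment_strength = 0.3`, the order of published conspecific
assortativity. These values were fixed once from the study description and
are not tuned.

What the generator deliberately does **not** emulate: movement kinematics
(co-occurrence is induced by co-assignment, not shared trajectories),
detection-range decay with distance, receiver downtime, tidal or
temperature covariates, and tag shedding. Passing tests therefore
demonstrate that the estimators recover the structure this generator
plants — seasonal peaks, region bias, conspecific excess — not that they
are robust to every artefact of real arrays.

## Validation scales and numerical choices

The acceptance-style suites run at desk scale, chosen as the package's own
testing conditions: 200 random schedules for SRI oracle equality, 100
random networks for assortativity oracle equality, 500 null simulations at
200 permutations for node-permutation calibration, 1000 null simulations
at 199 permutations for PERMANOVA calibration, and 100 simulation-fit
replicates each for seasonal peak recovery and social-assortment power.
Calibration bands ([0.03, 0.07] at α = 0.05) are the usual Monte-Carlo
windows at these replicate counts.

Numerical conventions worth recording: IRLS converges on relative deviance
change below `1e-8` with the linear predictor clamped to ±15 to survive
separation; permutation-tie comparisons use a `1e-8` relative tolerance;
integer percentages round half up (`pct_round()`), matching how cohort
tables are typeset; and every stochastic routine takes an explicit seed,
with identical scenario + seed yielding byte-identical synthetic data.

## Known limitations

- The seasonal model's term tests are approximate (penalized estimation,
  estimated dispersion); they are calibrated in simulation but make no
  claim to exactness, and EDF values need not match `mgcv`'s.
- The SRI treats hour bins as independent sampling periods; temporal
  autocorrelation within multi-hour visits inflates effective sample
  sizes, as it does in any gambit-of-the-group analysis at fixed bins.
- PERMANOVA's free-permutation p-values assume exchangeability of
  observations under the null; no restricted permutation schemes are
  provided.
- Detection probability is treated as constant within a scenario; no
  range-testing correction is applied.
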