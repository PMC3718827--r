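---
title: "Methods: envelope analysis, maximum-entropy suitability and warming projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope analysis, maximum-entropy suitability and warming projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefsuit)
```

# The problem

Biogenic reefs — here the model system is a horse-mussel-type bed-forming
bivalve — are priority habitats whose occurrence records are sparse,
presence-only, and spatially clustered. `reefsuit` implements a complete
desk-scale analysis for such data: delineate the environmental envelope the
known beds occupy, fit a presence-background maximum-entropy suitability
model, validate it with ROC/AUC against two background-sampling designs,
project it under a uniform linear ocean-warming trajectory, and account
suitable area per management region and epoch. Because the real gridded
layers (bathymetry, bottom temperature and salinity climatologies, seabed
landscape, current speed) are large external products, the package ships a
synthetic-data generator with a known ground truth, so every stage is
testable offline.

# Data model and geometry

Layers live on a regular lon/lat grid (default 0.005°), stored north-to-south
with the south-west corner as origin and half-open cells: a point belongs to
the cell found by flooring its coordinates against the cell edges, which
makes point-to-cell assignment unambiguous and testable. The Earth is a
sphere of radius 6371 km everywhere; one degree of a great circle is
111.1949 km; cell areas are `(Δ·111.1949)²·cos(lat)` km². A projected CRS
would change areas by well under the tolerances used anywhere downstream, and
avoiding it removes the GDAL/PROJ dependency (no R binding for either is
assumed; raster I/O is the plain-text ESRI ASCII grid dialect, and the
GeoTIFF dialect is declared but rejected with a clear message).

Seafloor slope (% rise/run) uses the Horn 3×3 kernel — the default of the
GIS in which the original analysis was done — with north-south spacing
`Δ·111.1949` km and east-west spacing scaled by `cos(lat)`. Border cells,
cells with a nodata neighbour, and cells that are themselves nodata are
nodata: any nodata input to a cellwise computation propagates.

# Environmental envelope analysis

1. **Population grouping.** Occurrences are grouped by single linkage under
   great-circle distance with a 10 km threshold: two records share a
   population iff a chain of records connects them with every hop ≤ 10 km.
   An optional, off-by-default rule treats pairs whose connecting chord
   crosses the land mask as unconnected — a reproducible proxy for the
   expert "obvious boundary" exclusions sometimes applied in this kind of
   analysis.
2. **Buffering.** Each record gets a 1 km disk standing for bed extent; a
   population's footprint is the union of its disks, rasterised and clipped
   to valid sea.
3. **Preferred ranges.** For each continuous variable the preferred range is
   the interquartile interval of the values at occurrence cells, pooled over
   populations, with quartiles by linear interpolation of order statistics
   (quantile type 7). The convention is declared so tests can be exact; the
   per-population alternative is not implemented.
4. **Landscape preference.** For each landscape class the inhabitation
   fraction is the share of populations whose footprint touches it;
   preferred classes are those with positive fraction at or above the median
   of the positive fractions. The maximum fraction is reported but plays no
   role in selection.
5. **Envelope.** A cell is in the envelope iff every continuous value lies
   in its closed preferred interval, its landscape class is preferred, and
   it is valid sea.

Two consequences worth knowing. The envelope is antitone in its constraints
(tightening an interval or removing a class never adds cells) — this is
property-tested. And the 1 km buffers can admit landscape classes *adjacent*
to the patches the beds actually occupy: on synthetic data with zero
contamination, every envelope cell satisfies the continuous ground-truth
intervals, but a minority of cells can carry a landscape class outside the
generating preference, admitted because buffers cross patch boundaries. A
green recovery test therefore establishes containment for the continuous
constraints and attributes any excess exactly to the landscape step.

# The maximum-entropy model

The model is a Gibbs distribution over background cells,
`raw(x) ∝ exp(λ·f(x))`, fitted by maximising

```
l(λ) = mean_presence λ·f(x) − log mean_background e^{λ·f(x)} − Σ_j β_j|λ_j|
```

Features are linear and quadratic terms per continuous variable, scaled to
[0, 1] by the background min/max, plus one indicator per landscape class;
hinge/product/threshold classes are named options that are rejected with a
message rather than silently accepted. Regularisation is
`β_j = β·sd_j(presence features)/√n_presence` with a floor of `β/n_presence`
so constant features stay penalised; `β = 1` by default. The L1 objective is
made smooth by splitting each weight into non-negative positive and negative
parts and running box-constrained L-BFGS-B, which is deterministic and
yields the KKT box condition `|presence mean − model mean| ≤ β_j` at the
optimum (property-tested, and cross-checked against an exhaustive
grid-search oracle on small worlds).

Predictions: `predict_raw` renormalises over the evaluation cells (a
distribution over the map); `predict_logistic` instead keeps the *training*
normaliser and applies the entropy-calibrated transform
`e^H·q(x)/(1 + e^H·q(x))`, `H` the entropy of the fitted distribution over
the training background. This choice makes the logistic output independent
of the evaluation extent and reproduces the standard identity that a
featureless model scores exactly 0.5 everywhere (equivalent to the published
default transform with τ = 0.5). Projection onto scenario stacks clamps
features to the training range — no extrapolation.

Background sampling is uniform over eligible cell centres with replacement:
the whole valid sea in `global` mode, or cells within 20 km of an occurrence
in `bias` mode; 10,000 points is the conventional default. The jackknife
refits with each variable alone and left out, reporting training gain
(log-likelihood improvement over the uniform distribution) and AUC without
each variable.

# Validation

The published description of the splitting procedure ("2-fold cross
validation" with 75/25 splits over ten replicates) is internally
inconsistent; it is implemented as repeated random hold-out (75/25 by
default, `round(fraction·n)` training records), which matches every other
detail. AUC is the rank-based Mann–Whitney statistic with ties counted one
half, exact against an all-pairs oracle. Test AUC scores held-out presences
against the training background of the same sampling mode (the
mode-per-column reading of the published comparison); whether fresh
background should be drawn is unstated in the source description, and
re-using the training background is declared. Rating thresholds: above 0.9
excellent, 0.7–0.9 good (both endpoints good, documented — the quoted rule
is ambiguous at the boundaries), 0.5 to below 0.7 poor, below 0.5 no better
than random.

# Warming scenarios

A single assumption: surface warming of 4 °C by 2100 from a 2009 baseline,
interpolated linearly and applied uniformly over space and depth. This gives
0.92, 1.80, 3.12 and 4.00 °C for 2030, 2050, 2080 and 2100 — reported to
2 decimals, and proportional to elapsed years exactly. Only temperature may
be perturbed; the interface rejects attempts to shift depth, salinity,
currents or landscape, which are held fixed under the scenario.

# Area accounting

Suitability maps are cut into ten half-open decimal bands (1.0 closed into
the top band) and three categories: most suitable (MS, 0.5–1.0), less
suitable (LS, 0.1–0.49), unsuitable (US, 0.0–0.09), read as half-open
decimal intervals so every probability has exactly one band and category
(0.095 is US, 0.495 is LS). Band and category areas per region (cell centres
assigned to the first containing polygon) satisfy partition identities that
are tested on every generated map. Percent loss is
`round((a0 − a_t)/a0·100)` with `"n/a"` at zero baselines. The
envelope-model comparison reports, per category, the percent overlapped by
the envelope, the combined overlap over MS∪LS, and an over-prediction
percent `(area(MS∪LS) − area(envelope))/area(MS∪LS)·100`. The
over-prediction formula is not given explicitly in the source material; this
area-difference form is adopted because it reproduces both published
comparison rows exactly from their printed inputs (26%/58% for the global
row, 16%/81% for the bias row), which the acceptance tests verify.

# The synthetic world

`synthetic_config()` defaults describe a 1°×1° mid-latitude shelf domain at
0.005° (200×200 cells): five smooth continuous fields built from
Gaussian-filtered white noise (filter σ = 12 cells), temperature with a
−2 °C/°lat gradient (cooler northwards), a contiguous land mask covering 10%
of the domain, a 4-class landscape of contiguous patches, and three
populations of 50 records each, rejection-sampled from a known truth
envelope, with population centres at least 3× the 10 km linkage threshold
apart and within-population scatter of 5 km. Contamination (occurrences
placed ignoring the truth) defaults to zero. All generators are
deterministic under the configured seed and leave the global RNG state
untouched.

The generator centres the temperature field on the species' thermal niche by
default, which places the population mid-range: under warming, habitat lost
in the south is partly replaced in the north, and the most-suitable area
need not decline monotonically. `truth_spec(domain_warm_bias = 2)` instead
offsets the domain 2 °C warmer than the niche centre — a population at its
warm range edge, the ecologically relevant configuration for a boreal
bed-forming species near its southern limit — and there progressive warming
can only erode habitat; the monotone-decline acceptance test uses exactly
this stated world. The analogous statement for the envelope holds once no
sea cell is colder than the envelope's cold edge (from that increment
onwards warming can only remove cells), and is tested from that increment.

What the generator does *not* emulate: real bathymetric texture, coastline
fractality, spatially correlated survey effort, or the covariance structure
of real oceanographic fields. A green test on synthetic data establishes
that the algorithms implement their stated contracts and recover a known
truth under the stated noise model — not that the package reproduces the
published UK-wide areas, which depend on proprietary-resolution inputs and
are explicitly out of scope.

# Numerical choices and edge cases

- Quantiles: type 7; degenerate value lists give zero-width intervals.
- Optimiser: L-BFGS-B on split weights, convergence tolerance well below
  the 1e-8 objective-improvement contract, iteration cap 1000, with the
  gradient norm reported on failure.
- Ties: points on shared cell edges floor into the cell whose south/west
  edge they touch; AUC ties count one half; the 0.9/0.7 rating boundaries
  both rate "good".
- Zero baselines in loss tables render "n/a" rather than dividing by zero;
  area gains appear as negative losses, not errors.
- Per-stage seeds are derived from one global seed by a small deterministic
  string hash (kept below 2³¹), so the end-to-end manifest hash is
  reproducible.

# Known limitations

- No GeoTIFF/GDAL support; ASCII grids only.
- No reprojection; areas assume the spherical small-cell approximation.
- Hinge and product features, cumulative output and replicate-GUI behaviours
  of the full published Maxent product are intentionally absent.
- Region polygons are assumed simple; cell assignment is by centre, so
  sliver regions thinner than a cell may receive no area.
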