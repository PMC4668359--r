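---
title: "Methods: marine protected-area representation gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marine protected-area representation gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpagap)
```

## The model

A representation gap analysis asks, for each species, what fraction of its
range lies inside protected areas. `mpagap` computes this on a regular
geographic grid (default 0.5°, 360 × 720 cells) because gridded occurrence
probabilities are the finest comprehensive description of marine species
distributions available, while protected-area boundaries are far finer
(often below 1 km²). The resolution mismatch forces one structural
assumption, made explicitly: *the protected share of a species' range in a
cell equals the protected share of the cell*. Writing `f_i` for the
protected fraction of cell `i` and `a_i` for its area,

    coverage = Σ_{i ∈ range} f_i · a_i  /  Σ_{i ∈ range} a_i .

When a species actually occupies only the unprotected part of a cell this
overestimates representation; every coverage figure the package reports is
therefore an upper bound in that specific sense.

A species is a **gap species** when no cell of its range has positive
protection. This is a topological condition, tested as exact emptiness of
the intersection between the range and the set of cells with `f_i > 0` —
never by comparing a floating-point ratio to zero, so a species covered by
an arbitrarily small sliver is *not* a gap species, which is the intended
semantics of "no overlap exists".

### Grid and areas

All computation stays in geographic coordinates on a spherical Earth
(R = 6371 km). The area of the cell bounded by latitudes φ₁ < φ₂ and a
longitude width Δλ is the exact band-slice formula
`R² · Δλ_rad · (sin φ₂ − sin φ₁)`. A sphere rather than an ellipsoid: the
discrepancy (< 0.4%) is far below the error introduced by 0.5° gridding,
and the sphere admits closed forms everywhere, which keeps the whole
pipeline free of quadrature. The cell-area field sums to 4πR² to 1e−6
relative tolerance (asserted in the test suite), areas are constant within
a latitude band and symmetric across the equator.

Rows run north to south from +90°, columns west to east from −180°; cells
are half-open (`[min, max)` on both axes) with +90° latitude and +180°
longitude clamped inward, so the bounds tile the globe with no gaps or
double counting. Indices are 1-based, as is idiomatic in R.

### Protected-area subsets

Protected-area registries are inconsistently attributed: the 'marine' flag
is sometimes absent on genuinely marine areas, and a large share of records
carries no IUCN management category. Instead of committing to one reading,
four subsets bracket the estate:

| subset | predicate |
|---|---|
| 1 | geometry overlaps at least one ocean cell |
| 2 | 'marine' flag set |
| 3 | 'marine' flag **and** IUCN category I–IV |
| 4 | ocean overlap **and** IUCN category I–IV |

Missing flags are treated as false and missing categories as `UNASSIGNED`,
which never passes the I–IV test — the conservative reading of an
incomplete field. Subset 3 is nested in 2 and 4 in 1 by construction, and
because species ranges live on ocean cells, per-species coverage is also
ordered 3 ≤ 2 ≤ 1 and 4 ≤ 1 (a flagged-but-landlocked polygon can enter
subset 2 without entering 1, but it contributes nothing to any ocean cell).
The ocean-overlap predicate uses a cell-level ocean mask rather than a
coastline polygon; at 0.5° the difference is a sliver of coastal cells, and
the mask keeps the predicate cheap and unambiguous.

### Rasterization

Each subset is dissolved and rasterized to per-cell protected fractions.
With no polygon-geometry engine involved, both steps reduce to one
primitive: the spherical area covered by a set of lon-lat straight-edged
rings, counted once where rings overlap. The package computes it exactly:

* each ring is clipped to the cell rectangle (Sutherland–Hodgman);
* a vertical-slab scanline places slab boundaries at every vertex longitude
  and every pairwise edge crossing, so within a slab the covered latitude
  intervals have fixed structure under the even-odd rule;
* each boundary edge contributes the closed-form integral
  `∫ sin(φ(λ)) dλ = Δλ (cos φ₁ − cos φ₂)/(φ₂ − φ₁)` (its limit `Δλ sin φ`
  for flat edges), which is the exact spherical area element for latitude
  linear in longitude.

There is no sampling and no quadrature, so the rasterizer's declared
accuracy (`rasterization_tolerance()`, 1e−9 relative) reflects only
floating-point accumulation. The even-odd rule makes self-intersecting
("bowtie") rings well-defined, which is how invalid registry geometries are
tolerated: repair consists of deduplicating vertices and dropping rings
with fewer than three distinct vertices or zero area; records left with no
geometry are dropped and counted. Point-only records are rejected outright
— buffering a point into a polygon of its reported area would invent
geometry the data does not contain. Rings crossing the antimeridian are
split at ±180° on ingest.

The fraction denominator is the **full** cell area, not the cell's ocean
portion. This keeps `fraction × area` arithmetic exact (total protected
area is recoverable as `Σ f_i a_i`) and matches how the coverage statistic
consumes the raster; an ocean-denominator variant would change `f_i` and
`a_i` in compensating ways for fully oceanic cells and inflate fractions in
coastal ones.

### Thresholding probability maps

Occurrence-probability maps assign each species a preferred core at
probability 1 with suitability decaying to 0 at the range limits. Presence
at threshold `t` means `probability ≥ t` for `t > 0`. At `t = 0` membership
is `probability > 0`: with a `≥` reading every species would occupy the
entire ocean, so the only sensible least-conservative range is "any
predicted suitability at all". Ranges are therefore nested in `t`, which
yields two theorems the test suite asserts on randomized worlds: the gap
count is non-decreasing and the median range size non-increasing as `t`
rises from 0 to 1. Species with no cells at a threshold have undefined
coverage; they are excluded from that threshold's summary and recorded in
an attribute rather than silently dropped (with the canonical
core-at-probability-1 structure this never happens for `t ≤ 1`).

### Representation bins

Species are binned by coverage `c`: gap (exact zero), 0–2% (0 < c < 0.02),
2–5% ([0.02, 0.05)), 5–10% ([0.05, 0.10)) and >10% (c ≥ 0.10). Printed bin
labels like "0–2%" and ">10%" are ambiguous at the boundaries; the package
closes interior boundaries on the left and places 10% in the top bin, so
that a species with exactly 10% of its range covered counts as meeting a
10% representation target. "Very low coverage" (used for density maps)
means `c < 0.02` *including* gap species; the gap-only and very-low maps
are produced separately.

### EEZ attribution

A species is attributed to an exclusive economic zone when at least one of
its range-cell centers falls inside an EEZ polygon. Cell-center membership
rather than polygon-cell area overlap is a documented approximation: at
0.5° it is cheap, unambiguous, and errs only for cells whose center and
bulk fall on opposite sides of a boundary. A species straddling several
EEZs counts once in the overall in-EEZ proportion but in each region's
tally; `region_cover_potential()` counts the gap species reachable from a
named region set (with `"HIGH_SEAS"` naming everything outside every EEZ),
which is monotone as regions are added.

## The synthetic world

The generator produces the full input set from one seed, with independent
RNG sub-streams per component so that, e.g., changing the MPA count leaves
the species draws untouched.

* **Ocean mask** — rectangular continental blocks laid down until a target
  ocean share (default 0.7, Earth-like) is reached.
* **Species** — ranges grown by seeded breadth-first accretion from a
  random ocean cell, giving contiguous blobs confined to ocean; range sizes
  in cells are log-uniform (heavy-tailed) scaled per taxon so mammals range
  an order of magnitude wider than sessile invertebrates; occurrence
  probability is 1 on a contiguous core (default 30% of cells) and decays
  linearly with accretion-layer distance, reaching 0 just past the range
  edge — the canonical core-plus-linear-decay structure of suitability
  models. Range seeds are coastally biased (default weight 6), reflecting
  the shelf concentration of marine biodiversity.
* **MPAs** — rectangles placed with a coastal bias (default weight 4), with
  management categories drawn from a mix that leaves a quarter unassigned
  and a 'marine' flag that is wrong or missing at a configurable rate
  (default 8%) — the attribute noise the four subsets exist to bracket.
* **EEZs** — coastal cell bands partitioned into longitude-banded regions:
  enough structure to exercise attribution and region counting with known
  truth.

Defaults (2° grid, 400 species, 700 MPAs of 0.5–2.5°) were chosen once as
a scaled-down world whose outputs sit in a realistic regime — a protected
estate of a few million km² under the strict subset, a gap share of a few
tens of percent, nearly all species under 10% coverage, medians of order
10⁶ km² falling roughly threefold across the threshold sweep — while a full
pipeline run stays in the tens of seconds. The test suite uses smaller
grids (5–10°, 20–60 species, up to 50 MPAs) for its randomized-world loops;
the acceptance checks run about a hundred such worlds.

**Known-coverage worlds.** For recovery testing the generator can build
worlds where true coverage is analytic: species ranges are grown disjointly
with probability 1 everywhere, and each species' MPA is assembled inside
its own range either from whole grid cells (truth is the nearest
cell-quantised value to the target, recorded) or from whole cells plus one
partial cell whose longitude width is solved exactly — spherical area is
linear in longitude width — so truth equals the target to machine
precision. The pipeline must reproduce cell-aligned truth to 1e−12 and
free-polygon truth to the rasterizer's declared tolerance.

**What the generator does not emulate:** real coastline geometry and
polygon complexity (multipart, holed, heavily vertexed MPAs), realistic
taxonomic richness patterns, environmental drivers of ranges (probabilities
are generated, not fitted), and the spatial autocorrelation of registry
attribute errors. Passing tests therefore demonstrate the *arithmetic and
order properties* of the pipeline on structurally faithful inputs, not
agreement with any real-world coverage figure.

## Numerical choices

* All areas in km², all coordinates in degrees, probabilities and coverage
  fractions dimensionless in [0, 1]; percentages only in reporting tables.
* Scanline slab boundaries include all pairwise edge crossings, so interval
  structure is constant within a slab; touching intervals merge under a
  1e−12° tolerance.
* Cell fractions are clamped to [0, 1] after division to absorb last-ulp
  overshoot.
* Gap status is carried as a boolean from the emptiness test; a gap
  species' covered area is set to exactly 0 so downstream equality tests
  are exact.
* Degenerate inputs: an empty polygon set rasterizes to the valid all-zero
  raster ("no MPAs"); empty species ranges are an error for coverage (no
  defined denominator); an empty region set has cover potential 0.
* Determinism: every generator draw descends from the root seed;
  `run_*()` commands write identical bytes on rerun, verified at the md5
  level in the tests, and manifests hash the configuration minus its output
  location.

## Limitations

Beyond the structural overestimation from the resolution mismatch, the
package deliberately does not model management effectiveness or
enforcement, does not cross-reference threat status, does not buffer
point-only protected-area records, and offers no site-selection or
complementarity tools — coverage maps indicate where representation is
poor, not where new protected areas should go.
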