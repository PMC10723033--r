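---
title: "Layered spot maps and hexbin summaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered spot maps and hexbin summaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotlayer)
```

## The visualization model

`spotlayer` renders multi-variable 2D data in one static panel by assigning
each variable to a distinct perceptual layer. The design rests on
figure-ground segmentation: humans parse a scene into a foreground object
and a background, and can read both at once. We map one variable to the
disc **fill** (the figure), a second categorical variable to a thin colored
disc **outline** (the ground), and optionally a third categorical variable
to a **glyph** drawn above the fill (the symbol). The outline works because
of the watercolor effect — a thin colored boundary induces a perceived
surface color — so even when spots are packed edge to edge the outline
colors read as contiguous background regions (cortical layers, anatomical
domains), not as 15%-width rings.

Three commitments follow from treating the roles as perceptual layers:

- **One disc per spot.** The ground and figure are realized as the stroke
  and fill of a single circle, not two concentric circles. This halves the
  element count and guarantees the outline is exactly adjacent to the fill.
- **Strict z-order.** Ground/figure discs precede symbol glyphs in paint
  order, always. In SVG output this is checkable textually: every spot is a
  `<circle class="spot">` with explicit `stroke` and `fill`, and all
  `class="glyph"` elements come later in document order.
- **Role constraints.** Ground and symbol layers require categorical
  variables (an outline gradient would defeat the region percept); fill
  accepts either kind. Each role may appear at most once.

### Parameters that matter

- `spot_diameter` (data units, required): the disc diameter. For Visium
  full-resolution pixel coordinates ~80–120 px reproduces the familiar spot
  map; the CLI defaults to 80% of the median nearest-neighbor spacing.
- ground `stroke_width` (data units, default 15% of `spot_diameter`): thin
  enough that the fill stays dominant, thick enough to carry color. Values
  above ~25% start reading as rings rather than background.
- Discrete palette: the Okabe–Ito colorblind-safe cycle, assigned to levels
  in byte-sorted order, so the same data always gets the same colors
  regardless of row order or session locale. Continuous fills use a
  256-step perceptually uniform colormap (`viridis` by default) over the
  `[min, max]` of non-missing values.
- `coord_mode`: `"image"` (y grows downward; the microscopy/Visium pixel
  convention, and the generator default for tissue) versus `"cartesian"`
  (embeddings). Rendering flips the axis for cartesian data; stored
  coordinates are never mutated, so I/O round-trips are exact.

### Degenerate inputs and missingness

A constant continuous fill column has zero range; rather than divide by
zero we map every spot to the colormap midpoint. Missing annotation values
(allowed everywhere except coordinates and ids) render neutral grey
(`#BDBDBD`); symbol layers simply skip spots whose level is missing or
unmapped. Overplotting order is ascending point id, so overlapping spots
are deterministic under row permutation.

## Hexagonal binning

Embeddings with 10^4–10^6 points overplot; binning into hexagons and
painting per-bin summaries is the standard remedy. We use pointy-top
hexagons in axial coordinates: cell `(q, r)` has center

```
x = x0 + s·√3·(q + r/2),   y = y0 + s·(3/2)·r
```

with circumradius `s`. The user-facing granularity knob is `nbins`, the
number of hexagon columns across the x-extent, so `s = x_range/(nbins·√3)`
and the extent's lower-left corner falls in cell `(0, 0)`.

**Assignment.** A point maps to the nearest cell center, computed by cube
rounding of fractional axial coordinates and then verified against the six
neighbors. Exact equidistance cannot be tested in floating point, so two
squared distances within `1e-9·s²` of each other are declared tied and the
tie resolves to the lexicographically smallest `(q, r)`. The same tolerance
and tie rule are used by the brute-force oracles in the test suite, making
"implementation equals exhaustive search" a well-posed assertion; random
points land inside the tie band with probability on the order of 1e-10.

**Aggregation.** Per occupied cell we report the point count, the
arithmetic mean of each continuous variable over non-missing members, and
for each categorical variable the full label tally plus the majority label,
ties again breaking to the lexicographically smallest tied label (so the
result is independent of input order). Cells with no points are simply
absent. When a categorical variable has missing values, tallies count
non-missing members only — so `count` equals the tally total exactly when
the variable is complete. The per-cell tally is kept in the aggregate (and
in the CLI's `--table-out` TSV) because a majority label can hide
substantial intermixing within a hexagon; consumers who care can inspect it.

**Region boundaries.** Convex hulls drawn around label regions overlap,
which is exactly the ambiguity binning was meant to remove. Instead, for
every occupied cell and each of its six edges we emit the edge into the
cell's majority-label segment set iff the neighbor across that edge is
unoccupied or has a different majority. Edges interior to a same-label
region vanish; an edge between two different-majority cells is emitted once
into *each* label's set (both sides drawn at full width, later label in
sorted order painted on top — the two-sided convention keeps each label's
outline closed). Region interiors of distinct labels therefore never
overlap by construction.

A geometric detail makes this exact rather than tolerance-based: every
hexagon vertex lies on the integer half-step lattice
`(x0 + s·√3/2·i, y0 + s/2·j)`, so segments are stored as integer 4-tuples,
deduplication and the even-vertex-degree closure property are exact integer
computations, and conversion to data units happens only at draw time.

One property we assert empirically but do not claim as a theorem: doubling
`nbins` never decreased the number of occupied cells in any of our seeded
tests. It is a strong regularity for scattered data, but child hexagons are
not nested inside parent hexagons, so adversarial configurations could
violate it; we test it under fixed seeds rather than advertise it as an
invariant.

## What the synthetic generators emulate

Both generators pin the RNG (Mersenne–Twister, inversion normals, rejection
sampling) inside the call and restore the caller's RNG state, so a seed
plus parameters is a complete recipe for the bytes of the output table.

`make_layered_tissue()` emulates a spot-based section of layered cortex:
spots on a hexagonal lattice with 100-unit center-to-center spacing (round
numbers; correctness nowhere depends on the true Visium 100 µm pitch),
horizontal equal-height bands labeled `L1..L(n-1)` plus `WM`, and a
four-state `coloc_status` per spot (`none/geneA/geneB/both`) with baseline
probabilities 0.70/0.13/0.11/0.06 — a minority of spots express either
gene of a ligand-receptor pair, and double-positives are rarest. In the
enriched band the probability of `both` is multiplied by the enrichment
factor and the four probabilities renormalized; the recorded truth includes
the implied ratio `Pr(both|enriched)/Pr(both|other) = e/(1+(e−1)·p_both)`,
which for the default `e = 4` is ≈ 3.39. What it does **not** emulate:
spatial autocorrelation within bands, curved laminae, counts for a full
transcriptome, or the upstream cell-cell-communication analysis that would
produce real colocalization calls — the status is an input here, as it is
for the plotting layer.

`make_mixture_embedding()` emulates a clustered single-cell embedding: `k`
isotropic Gaussian clusters with means on a circle of radius 10 and
`sigma = 1` (≈ 11.8σ nearest-mean separation — deliberately well separated,
because the recovery guarantee we test is *conditional on separation*), and
a lognormal `expr` whose log-mean is 1.5 in designated clusters and 0
elsewhere (`sdlog = 0.5`), i.e. one marker gene. Real UMAPs have curved,
touching, variable-density clusters; consequently a passing majority-label
recovery test here says the binning machinery is correct, not that hexagon
majorities are trustworthy near real cluster borders — there the per-cell
tally is the honest readout.

## Verification strategy and problem sizes

Every geometric operation is tested against an independent brute-force
oracle that re-derives the geometry differently (exhaustive nearest-center
search; trigonometric vertex positions snapped to the lattice; per-edge
neighbor lookup by matching geometric centers): 2,000 uniform points on a
20×20-column grid for assignment, 500 mixture points for aggregation
(tallies exact, means within 1e-12 relative), 100 random occupancy/label
patterns on grids up to 12×12 for boundaries. Parameter recovery runs at
10,000 cells / 5 clusters and 20,000 spots / enrichment 4, where the
empirical enrichment ratio has a ~5% standard error against the ±10%
acceptance band. These sizes keep the full suite under half a minute while
leaving comfortable statistical margins. `scripts/acceptance.R` recomputes
all of it from a command-line seed.

## Design choices that were genuinely open

- **CLI symbol syntax.** The glyph map micro-syntax is
  `--symbol VAR=level:glyph[,level:glyph...]`; the variable name is
  explicit because nothing else in the invocation identifies which column
  carries the highlighted levels.
- **Two-sided boundary edges.** An edge between two occupied cells with
  different majorities belongs to both regions; we emit it into both
  segment sets and draw both at full width (sorted-label order on top).
  The alternative — half-width strokes per side — is visually subtler but
  makes "each label's outline is a closed cycle" false.
- **Missing-value policy.** Grey-out rather than drop: dropping spots would
  silently distort the spatial lattice, and the grey disc keeps the
  neighborhood structure legible.
- **Integer columns default to continuous.** Expression counts are
  integers; cluster ids read from CSV must be explicitly overridden to
  categorical (`kind_overrides = c(cluster = "categorical")`).

## Limitations

No interactive output, by design — the point is a static panel that
survives print. No hatching fills for dense single-cell overplotting, no
polygonal per-cell morphology rendering, no HDF5/h5ad ingestion, and no
within-hexagon subdivision for mixed cells (the tally is surfaced instead).
Hexbin legends show the fill colorbar and boundary label colors but not
per-cell counts; use `write_hex_table()` for the quantitative view.
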