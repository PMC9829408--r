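---
title: "Methods: redundant color + hatch coding of point groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redundant color + hatch coding of point groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatchplot)
```

## The model

hatchplot encodes a categorical variable over a 2-D point cloud with two
channels at once: a fill color and a hatch pattern. The design assumption
is that single-cell scatter plots are *mixtures* of regimes — compact
dense clusters where individual markers merge into blobs, and isolated
points where only the marker itself is visible — and that the two regimes
need different pattern carriers. Dense regions can carry a coarse
area-filling hatch; isolated points can only carry a glyph drawn on the
marker itself. The pipeline is therefore: classify each point, hatch the
dense regions, stamp the sparse points.

Everything downstream of the data-to-canvas transform operates in
*display coordinates* (typographic points). This is deliberate:
legibility is a property of the rendered page, so a 45° pattern must look
45° whatever the data aspect ratio, and "dense enough to hatch" must mean
"markers visually merge", which depends on marker size and canvas size,
not on data units. The cost is that classification needs the canvas
geometry up front; `grid_config(bin_size = )` provides a direct override
for headless or data-unit workflows.

## The sparse/dense detector

Points of each group are binned on a square grid with half-open cells
(left/bottom edge inclusive — the tie-break for points exactly on a cell
border). A cell is a *dense candidate* when the 3×3 block of cells around
it holds at least `density_threshold` same-group points, counting the
cell itself. Candidates form dense regions via 8-connected components
(diagonal chains of touching markers read as one cluster), and components
smaller than `min_cluster_cells` cells are discarded, which removes
incidental pairs that would otherwise receive a one-cell "region".
Points in surviving cells are dense; everything else is sparse. Groups
are processed independently: one group's geometry never influences
another's labels, which property tests verify by relabeling bystander
groups.

Tunable parameters, with units and defaults:

| parameter           | default               | units   | rationale |
|---------------------|-----------------------|---------|-----------|
| `point_size`        | 3                     | pt      | marker diameter; typical for 10k-point panels |
| `bin_factor`        | 1.5                   | —       | bin side = 1.5 × marker diameter: two markers in one bin visually overlap |
| `density_threshold` | 4                     | points  | a 3×3 neighborhood with ≥ 4 markers reads as a blob at default sizes |
| `min_cluster_cells` | 2                     | cells   | a single hot cell is still an outlier clump, not a cluster |

Raising `density_threshold` can only shrink the dense set (the
neighborhood count is fixed per cell, and discarding candidates can only
remove component cells); this monotonicity is asserted as a property
test. The detector is intentionally linear-time and deterministic; it is
validated against a brute-force oracle (exhaustive O(n²) neighborhood
counts plus explicit flood fill) on random multi-group configurations.

Users can bypass the detector entirely with a sparse-point id list
(`apply_sparse_override()`); the listed points become sparse, all others
dense, and the provenance flag records that the labels did not come from
the detector.

## Hatch geometry

A region mask is the union of the occupied square cells of a group's
dense points — deliberately un-smoothed. An alpha-shape or concave hull
would look rounder but behaves badly on concave and fragmented clusters;
the blocky union is robust, cheap, and visibly "coarse", which suits a
background texture. For each pattern line family at angle θ, parallel
lines are placed at perpendicular offsets `phase + n·spacing` measured
from the mask bounding box's low edge along the family normal, with
`phase = spacing/2` by default so even a one-cell mask receives a line.
Each line is clipped against every nearby cell (Liang–Barsky slab
clipping) and overlapping parameter intervals are merged (tolerance
10⁻⁹ × bin) so a line crossing many cells emits one maximal segment per
run. Default region spacing is 4 × line width; default line width is
0.15 × marker diameter; default line color is the group fill darkened
40% toward black.

Sparse-point glyphs are chords of the marker disk at the same family
angles, offsets `m · glyph_spacing` centered on the marker
(`glyph_spacing = marker_radius` by default, so each family contributes
its diameter chord), endpoints exactly on the marker circle. Glyph lines
default to white on dark fills (linear-light luminance < 0.5) and to the
darkened fill otherwise, for contrast against both the marker and the
page.

Correctness is checked two ways: per-line hatched length against a
dense-sampling oracle (step = bin/2000; agreement required within 1%,
with an absolute floor of 50 sampling steps for lines below the oracle's
own resolution), and a spacing-semantics sanity check that total length ×
spacing approximates a convex mask's area within 10%.

## Patterns, palette, and capacity

The seven stock patterns map to angle sets {0}, {90}, {45}, {135},
{0, 90}, {45, 135} and {} (blank). The two-family geometries for `cross`
and `checkers` are this package's convention: the six non-blank patterns
are then pairwise distinct as one- and two-family line sets, which is the
property that matters for decoding. Custom patterns are any angle list in
[0°, 180°]; 180° is normalized to 0° because line families are
undirected. Resolution fills missing aesthetics from defaults and is
idempotent.

The default palette embeds 40 colorblind-friendly hex values following
the dittoSeq convention (Okabe-Ito base hues plus darkened/lightened
variants). Assignment is color-major: group *n* (0-based) gets color
*n* mod 40 and pattern ⌊*n*/40⌋ mod 7, so plots with ≤ 40 groups use
distinct colors with a shared first pattern, and the first 280 groups get
pairwise-distinct (color, pattern) codes. A 281st group under defaults is
a capacity error rather than a silent collision.

## CVD simulation

The audit uses the published Machado–Oliveira–Fernandes severity matrices
(protan, deutan, tritan; severities 0–1 tabulated in 0.1 steps, linearly
interpolated) applied in linear-light RGB, plus a monochromacy transform
that interpolates toward the Rec. 709 luma projection. Severity 0 is the
identity and all rows sum to 1, so grays are fixed points — both are
tested, and the anomalous-trichromacy path is cross-checked channel-exact
against an independent linear-light implementation. Palette separability
is summarized as the minimum pairwise CIEDE2000 distance after
simulation.

One wording choice: protanomaly here is the standard *red-weak*
deficiency. Texts that describe a blue-yellow axis are describing
tritanomaly, which is provided as its own deficiency type, so both
readings are available.

The audit's central invariant is structural: recoloring a rendered figure
through any deficiency changes style colors only; segment counts,
endpoints, angles and widths are bit-identical. The information carried
by the pattern channel therefore survives any color collapse — including
full monochromacy, under which the 40-color palette's minimum separation
does reach zero (lightness variants collide in gray).

## Synthetic data

Two generators make every stage testable without external data, with one
explicit seed parameter and no global RNG state.

`make_embedding_fixture()` emulates a clustered embedding: per group, an
isotropic Gaussian blob (`blob_sd = 1` data unit) plus a sparse halo
uniform by area in the annulus from `halo_radius/2` to `halo_radius`
(default 20), blob centers placed deterministically at equal angles on a
circle of radius 20. Defaults are 4 groups × (2400 dense + 100 sparse) =
10,000 points. The halo parameters were chosen once, from the geometry of
the default detector: at a 20:1 blob-to-halo scale ratio the expected
number of halo neighbors inside a 3×3 bin window is well below the
density threshold, so planted halo points are genuinely sparse to the
detector rather than borderline.

`make_spatial_fixture()` emulates a tiled microscopy acquisition: an
`n_frames_x × n_frames_y` grid of square tiles, each tile one group with
uniform points; the 2 × 41 default reproduces the many-group regime of 82
frames.

What the fixtures do *not* emulate: anisotropic or curved manifolds,
group-overlapping clusters, density gradients within a cluster, and
frame-to-frame cell-count variation. Passing label-recovery tests on
these fixtures therefore shows the detector separates well-separated
scales; it does not certify behavior where dense and sparse scales blend
continuously — there the boundary is necessarily a judgment call made by
the thresholds above.

## Numerical choices and degenerate inputs

- Cell indexing adds 10⁻⁹ of a bin before flooring so points computed to
  sit exactly on a cell boundary bin into the inclusive (left/bottom)
  cell despite floating-point noise.
- A degenerate data range (all x or all y equal) is expanded to one unit
  so the display transform stays finite.
- Interval merging in the hatch clipper uses a 10⁻⁹ × bin tolerance;
  component ordering is row-major by minimal cell, making all outputs
  order-deterministic.
- SVG numbers are written as fixed three-decimal strings (with a
  negative-zero normalization), which is what makes output byte-stable
  across platforms.
- PDF export blanks the `/CreationDate` and `/ModDate` payloads in place,
  preserving byte offsets, so repeated exports are also byte-identical.

## Problem sizes in the test suite

Unit and property tests run on configurations of tens to hundreds of
points; oracle-equivalence suites use 50 random ≤ 20×20-cell
configurations (classification) and 20 random masks (hatch length);
end-to-end tests use the 10,000-point embedding fixture and the 82-group
spatial fixture. These sizes make the whole suite run in seconds while
still exercising every contract at the scale the defaults target.

## Known limitations

- Overlapping groups overdraw in input order; there is no blending or
  interleaving strategy for co-located clusters.
- Region masks are blocky by design; there is no boundary smoothing.
- The legend lays out in fixed-width columns and does not auto-shrink for
  hundreds of groups.
- Continuous variables (colormaps) are out of scope; the encoding is
  categorical.
- No readers for single-cell container formats; input is a delimited
  table (or a data frame built in R).
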