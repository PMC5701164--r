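---
title: "Relative-constraint design of paper-based microfluidic devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative-constraint design of paper-based microfluidic devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upadcad)
```

## The problem and the model

Microfluidic paper-based analytical devices (µPADs) move fluids through
hydrophilic paper channels bounded by hydrophobic (typically wax) barriers.
Three-dimensional devices stack patterned paper with double-sided adhesive
film; fluid crosses between layers only where zones overlap, and those
zones must be concentric or capillary flow becomes irreproducible and the
device fails. In a general-purpose drawing program every element has an
absolute position, so a one-parameter design change — lengthening one
channel — forces manual repositioning of everything downstream of it on
every layer.

`upadcad` instead represents a device as a *forest of relatively placed
shapes*. Each node carries a shape (circle, rectangle, polygon, or text),
a layer index, and a placement relative to its parent: an angle θ
(degrees, counter-clockwise, 0 along +x, y up), a distance, and an
attachment rule. Resolution walks the tree once:

* `attach = "center"` — the child's anchor is
  `parent + dist·(cos θ, sin θ)`;
* `attach = "abut"` — the child is pushed out along θ until its near
  boundary touches the parent's boundary, computed from the *support
  extents* of the two footprint polygons along θ (plus `dist` of
  clearance). Rectangles attached this way lie lengthwise along θ with
  their anchor on the near edge.

Distances and dimensions may be arithmetic expressions over named design
parameters, evaluated at resolve time. Editing a parameter or a node
property therefore repositions exactly the edited node's subtree — the
refactoring guarantee — and `diff_positions()` certifies it by comparing
two resolutions element by element.

### Why the abut anchor sits on the near edge

The anchor choice is the one genuinely open semantic decision, and it is
load-bearing. With the anchor at a channel's near edge, changing only the
channel's *length* leaves its own anchor fixed while its far-end
descendants move. Consequently an edit to one channel repositions only
*other* elements, and editing *n* parallel channels moves exactly *n*
times the per-channel descendant count — the bookkeeping stays additive.
Had the anchor been the rectangle's centroid, every length edit would also
move the edited element and the arithmetic would not compose.

### Cross-layer connections and adhesive holes

A child may sit on its parent's layer, an adjacent layer, or two layers
away when the intervening layer is adhesive. In the last case a
normalization pass (`auto_holes()`) inserts a circular hole node on the
adhesive layer — diameter the minimum of the two connected flow widths,
placement inherited from the child, child re-parented concentric on the
hole. Holes are ordinary first-class elements: they are counted, diffed,
rendered (adhesive layers emit cut outlines), and they travel with their
subtree under refactoring. Because dist-0 placements use `cospi`/`sinpi`,
stacked zones are concentric *exactly*, not to within rounding:
`check_alignment()` at tolerance 0 returns no violations on any shipped
fixture.

## The script format

Designs serialize to a line-oriented UTF-8 text format (`.apad`): header
directives (`device`, `param`, `layer`, `default`, `sheet`), then one line
per node, depth encoded by a run of `>` characters. `$CUT` on a layer line
is accepted as an alias for the `cut` render mode. `#` comments to end of
line; the decimal separator is always `.` regardless of locale.
Expressions are stored as strings and evaluated only at resolve time, so a
saved script refactors exactly like an in-memory design. Serialization is
canonical and deterministic: the suite asserts parse ∘ serialize is the
identity on all six fixtures and on randomly generated designs, and that
the canonical form is a byte-level fixed point.

Expression evaluation is deliberately tiny: `+ - * /`, parentheses, unary
minus, numeric literals and declared parameter names. The string is
charset-checked, identifiers are whitelisted against the parameter table,
and the parsed syntax tree is walked with only those operators permitted —
a malformed or adversarial script cannot evaluate anything else.

## Geometry

Polygon union, offsetting and clipping are delegated to the Clipper
library (`polyclip`), with a fixed absolute resolution of 1e-9 mm so
results do not depend on a device's coordinate magnitudes.

* **Circles** are regular 128-gons (configurable via
  `options(upadcad.circle_segments=)`). Offsets of true circles are
  transcendental, so all area and length assertions in the suite carry a
  0.5 % tolerance; at 128 segments the polygonalization error is an order
  of magnitude below that.
* **Connectivity** ("one hydrophilic network") counts touching as
  connected, because an abutting channel/zone pair must form one flow
  path. Contact is tested by offsetting one footprint by 1 µm and
  intersecting — robust against the exact-tangency cases that boolean
  unions resolve unpredictably. Components come from `igraph` over the
  pairwise contact graph.
* **Snap-to-shape buffering** is `(union ⊕ w) \ union`: a constant-width
  ring hugging each flow network, never entering it. Rings of nearby
  groups are merged by a final union. The full-field mode is canvas minus
  the flow union. Both modes leave identical white flow area; buffered
  wax area is never larger — asserted per layer in the suite.
* **Cut outlines** are the union boundary rings, outer rings
  counter-clockwise and holes clockwise, with a nominal stroke width
  (default 0.2 mm).

Default border width is 1.5 mm and default cut stroke 0.2 mm — unstated
upstream, chosen within common wax-printing practice and overridable per
design.

## Rendering and page layout

Masks are drawn on a cairo PNG device with antialiasing disabled, in user
coordinates that *are* millimetres, so every pixel is pure black or white
and pixel dimensions equal physical extent × dpi rounded up (default
600 dpi). One canvas — the design-wide bounding box plus a margin — is
shared by all layers so masks stay co-registered. Text renders through
R's built-in Hershey vector fonts, making output independent of the fonts
installed on a machine; in full-field mode labels are knocked out white
(black-on-black would be invisible), in buffered and cut modes they print
black. The text footprint used during *layout* is a nominal
0.6 × height × nchar box rather than measured glyph metrics, keeping
resolution deterministic and device-free; text is decor and never joins a
flow network, so this approximation cannot affect fluidic geometry.

PDF sheets embed the exact physical page size (pages may be declared in
inches, converted at 25.4 mm/in) and tile the device row-major:
`n_cols = ⌊(W − 2m + s)/(w + s)⌋`, rows analogous, leftover space at the
right and bottom — the simplest deterministic rule. The package emits one
page per layer; when several distinct layers must share a physical sheet,
that is what the origami combined-layer grid is for.

Origami fold sheets reuse layer designs under isometries: reflection (if
any) then rotation by a multiple of 90°, about the source canvas centre,
then translation into a grid cell (rows run downward). The suite checks
all pairwise distances survive to 1e-9 mm.

## The fixtures: what they emulate, and what they do not

The six generators under `make_case_study()` are the package's synthetic
input surface. They reproduce the *structure* of six archetypal devices —
a single-layer 1→3 splitter, a 96-zone microzone plate with labels, a
cut-path 2DPN, a 5 paper + 5 adhesive immunoassay stack, the 4-sample
multilayer splitter, and a 3×3 origami grid built from three unique
layers. Their absolute dimensions (3 mm zones, 1 mm channels, 9 mm plate
pitch, …) are configurable defaults, not published values; nothing in the
test surface depends on them. The 2DPN, immunoassay and origami interior
artwork is schematic: layer counts, materials and render modes are
faithful, the decorative geometry is not. Passing tests therefore
demonstrate the layout, counting and propagation machinery, and the
geometric guarantees on these structures — they say nothing about how
melted wax spreads in real paper (barrier widths here are nominal
pre-melt patterns), nor whether a particular origami sheet folds into
working fluidic contact.

The multilayer splitter deserves its numbers spelled out. With *s*
samples and fan-outs (2, 2, 4), each stage unit is one inlet + *f*
channels + *f* outlets, holes mirror inlet/terminal counts on the
adhesive layer above, giving per-layer counts
(*s*, *s*, 5*s*, 2*s*, 10*s*, 4*s*, 36*s*, 16*s*, 16*s*) — at *s* = 4:
(4, 4, 20, 8, 40, 16, 144, 64, 64), 364 in total. One first-stage
channel's proper descendants are 1 + 5 + 18 + 8 = 32 paper and
1 + 2 + 8 = 11 adhesive elements: 43 moved per edit, 344 for all eight.
The suite verifies these against a brute-force subtree-traversal oracle,
and `scripts/acceptance.R` recomputes them from scratch.

## Numerical choices

* Angles evaluate through `cospi`/`sinpi`; axis-aligned and dist-0
  placements are exact, so alignment residuals are exactly zero and the
  position-diff tolerance of 1e-6 mm sits ~9 orders of magnitude above
  float noise while any true motion sits well above it.
* Children resolve in declaration order; ids are stable under
  refactoring, so diffs are well defined. Duplicate ids are a validation
  error (they are how an aliasing cycle manifests in a value-semantics
  tree).
* Degenerate inputs are data, not crashes: `validate()` returns a
  violation table (undeclared layers, non-simple polygons, non-positive
  dimensions, non-finite or negative distance expressions, bad layer
  jumps), and `resolve_design()` refuses designs with violations.
* Suite problem sizes are deliberately desk-scale: refactoring closure is
  property-tested on 1,000 random trees of ≤ 9 nodes, masks render at
  100–300 dpi, and the whole suite runs in well under a minute.

## Known limitations

No capillary-flow or volume simulation; no constraint solving beyond tree
propagation (no simultaneous constraints, no collision avoidance — a
careless fixture can draw overlapping branches); no folding-feasibility
prediction for origami sheets; membrane is carried as a material tag with
no distinct behavior; and the GUI-style live preview of the original
interactive workflow is out of scope — the batch functions, the CLI
wrapper and the script format are the interface.
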