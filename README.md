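# upadcad

Relative-constraint CAD for microfluidic paper-based analytical devices
(µPADs).

µPADs are patterned sheets of paper whose hydrophilic channels wick fluids
by capillarity. Multi-layer devices are stacked from patterned paper and
double-sided adhesive, and they only work if the zones of adjacent layers
overlap exactly — a single design change in a drawing program means
manually repositioning every downstream element on every layer. `upadcad`
removes that step: a device is a **tree of connected shapes** in which
every zone or channel is placed relative to its parent by an angle θ, a
distance *d* and an attachment rule, so no element carries an absolute
coordinate. A child attached by its centre resolves to

```
p_child = p_parent + d · (cos θ, sin θ)
```

while an abutting channel starts at its parent's rim (the support extent
of the parent footprint along θ) and runs lengthwise along θ. Distances
and dimensions may be arithmetic expressions over named parameters
(`dist = "2*L"`), evaluated at resolve time — so editing one number
re-lays-out the whole device, across layers, including the auto-generated
holes in the adhesive films that bond the stack.

The package provides:

* a plain-text `.apad` script format (parse / serialize / round-trip);
* the layout engine: resolve to absolute per-layer geometry, refactor by
  parameter or node edits, diff two resolutions, count elements, check
  cross-layer alignment;
* polygon services (via the Clipper library): connected flow networks,
  "snap-to-shape" buffered wax borders, full-field wax masks, cut
  outlines for knife plotters and laser cutters;
* outputs: binary PNG masks at any dpi, stroke-only SVG cut paths,
  physically-dimensioned PDF sheets with automatic row-major page tiling,
  and origami fold sheets that reuse transformed layer copies;
* six case-study device generators (`make_case_study()`), from a
  single-layer sample splitter to a 364-element multilayer splitter and an
  origami grid, plus a miniature refactoring demonstrator
  (`make_figure2_device()`).

## Worked example

The four-sample splitter fans each inlet through 1→2, 1→2 and 1→4 split
stages across alternating paper/adhesive layers, ending in 64 test zones:

```r
library(upadcad)

d <- make_case_study("splitter3D")      # 4 samples, stages 2-2-4
count_elements(d)
#> $per_layer
#>   1   2   3   4   5   6   7   8   9
#>   4   4  20   8  40  16 144  64  64
#> $total
#> [1] 364
```

364 elements over 9 layers — the even (adhesive) layers hold only
auto-generated registration holes. Now lengthen a single rectangular
channel of the first split stage (on the second paper layer) and let the
layout refactor itself:

```r
before <- resolve_design(d)
edited <- refactor_design(d, nodes = list(s1_c1 = list(len = "len1+5")))
diff_positions(before, resolve_design(edited))
#> <pad_diff> 43 element(s) moved (tolerance 1e-06 mm)
#>   by material: paper=32 adhesive=11
#>   by layer:    3=1 4=1 5=5 6=2 7=18 8=8 9=8
```

One number changed; 43 downstream elements — 32 on paper layers, 11 on
adhesive layers — moved to keep every cross-layer connection concentric
(the edited channel's own anchor stays put: it grows from its inlet).
Editing the shared length parameter moves all eight first-stage subtrees
at once:

```r
diff_positions(before,
               resolve_design(refactor_design(d, params = list(len1 = 13))))
#> <pad_diff> 344 element(s) moved (tolerance 1e-06 mm)
```

Deliverables come from the same design object:

```r
apad_compile(d, "out/")        # 9 PNG masks, 4 cut SVGs, tiled PDF, script
render_layer(d, 1, dpi = 600)  # binary wax mask of the top layer
tile_sheet(d, sheet_spec(in_mm(8.5), in_mm(11)), "sheet.pdf")
```

A thin command-line wrapper lives at `inst/cli/autopad.R`
(`compile`, `diff`, `validate`, `fixtures` subcommands).

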