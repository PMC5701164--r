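Package: upadcad
Title: Relative-Constraint Design of Paper-Based Microfluidic Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A scriptable computer-aided design system for microfluidic
    paper-based analytical devices (uPADs). Devices are described as trees
    of connected shapes in which every zone or channel is positioned
    relative to its parent, so that editing a single parameter re-lays-out
    an entire multi-layer device automatically. From one plain-text design
    script the package resolves absolute geometry per layer, generates
    wax-print masks (full-field or shape-fitting buffered borders), cut
    outlines for knife plotters and laser cutters, auto-generated adhesive
    hole layers, origami fold sheets built from transformed layer copies,
    and physically-dimensioned, page-tiled PDF print files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    igraph,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
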