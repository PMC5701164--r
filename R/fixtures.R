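# Programmatic generators for the six case-study device designs. Absolute
# dimensions (zone diameters, channel widths, pitches) are configurable
# defaults chosen within common wax-printing practice; everything the test
# surface asserts about these designs depends only on counts and topology,
# never on the default dimensions. The 2DPN, immunoassay and origami
# internal geometries are schematic: they carry the right layer stack,
# materials and render modes, not any published artwork.

#' Build one of the six case-study device designs
#'
#' \describe{
#'   \item{splitter1L}{single-layer device splitting one sample into three
#'     test zones: 1 inlet + 3 channels + 3 zones, one connected
#'     hydrophilic network; the snap-to-shape buffering showcase.}
#'   \item{microzone96}{a 96-well paper microzone plate: an 8 x 12 array
#'     of circular zones at uniform pitch with row letters and column
#'     numbers as text labels.}
#'   \item{twoDPN}{a two-dimensional paper network on a single cut-mode
#'     membrane layer: channels are cut out rather than wax-bounded, and
#'     each connected piece yields one plotter outline.}
#'   \item{immunoassay3D}{a vertical-flow sandwich immunoassay stack: five
#'     patterned paper/nylon-membrane layers interleaved with five
#'     patterned adhesive films, the interior four of which receive
#'     auto-generated registration holes; one lateral channel length
#'     parameter refactors the whole stack.}
#'   \item{splitter3D}{the multilayer sample splitter: `samples` inlets
#'     each split through the `plan` fan-out stages (default 2, then 2,
#'     then 4) across alternating paper/adhesive layers, ending in
#'     `samples * prod(plan)` test zones. Defaults give 4 samples -> 64
#'     zones, 364 elements over 9 layers.}
#'   \item{origami}{an origami fold-sheet device: three unique layer
#'     patterns; the fold sheet is a 3 x 3 grid that reuses the first
#'     row's three layers under 180-degree rotation in the middle row
#'     (grid available via [origami_grid()]).}
#' }
#'
#' @param which fixture id.
#' @param overrides named list of configuration overrides; names must match
#'   the fixture's knobs (see the generator functions' arguments).
#' @return A validated [pad_design()].
#' @export
make_case_study <- function(which = c("splitter1L", "microzone96", "twoDPN",
                                      "immunoassay3D", "splitter3D",
                                      "origami"),
                            overrides = list()) {
  which <- match.arg(which)
  f <- switch(which,
    splitter1L = make_splitter1L, microzone96 = make_microzone96,
    twoDPN = make_twoDPN, immunoassay3D = make_immunoassay3D,
    splitter3D = make_splitter3D, origami = make_origami)
  unknown <- setdiff(names(overrides), names(formals(f)))
  if (length(unknown))
    stop("unknown override(s) for ", which, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  design <- do.call(f, overrides)
  viol <- validate(design)
  if (nrow(viol)) stop("fixture '", which, "' failed validation", call. = FALSE)
  design
}

make_splitter1L <- function(arm = 9, zone_d = 4, center_d = 6,
                            channel_w = 1.2) {
  arms <- lapply(seq_len(3), function(i) {
    a <- c(90, 210, 330)[i]
    pad_node(paste0("ch", i), rect_shape("arm", channel_w),
             placement(angle = a, attach = "abut"),
             children = list(
               pad_node(paste0("zone", i), circle_shape(zone_d),
                        placement(angle = a, attach = "abut"))))
  })
  pad_design("splitter1L",
             params = list(arm = arm),
             layers = list(pad_layer(1, "paper", "wax_buffered")),
             roots = list(pad_node("center", circle_shape(center_d),
                                   layer = 1, children = arms)))
}

make_microzone96 <- function(rows = 8, cols = 12, pitch = 9, zone_d = 6,
                             label_h = 4) {
  zone <- function(r, c) sprintf("%s%d", LETTERS[r], c)
  col_chain <- function(r, c) {
    kids <- list()
    if (c < cols) kids <- list(col_chain(r, c + 1))
    if (r == 1)
      kids <- c(kids, list(pad_node(paste0("col", c),
        text_shape(as.character(c), label_h),
        placement(angle = 90, dist = pitch * 0.9))))
    pad_node(zone(r, c), circle_shape(zone_d),
             if (c == 1) placement() else placement(angle = 0, dist = pitch),
             children = kids)
  }
  row_node <- function(r) {
    head <- col_chain(r, 1)
    head$placement <- if (r == 1) placement()
                      else placement(angle = 270, dist = pitch)
    kids <- list(pad_node(paste0("row", LETTERS[r]),
      text_shape(LETTERS[r], label_h),
      placement(angle = 180, dist = pitch * 0.9)))
    if (r < rows) kids <- c(kids, list(row_node(r + 1)))
    head$children <- c(head$children, kids)
    head
  }
  root <- row_node(1)
  root$layer <- 1L
  pad_design("microzone96",
             layers = list(pad_layer(1, "paper", "wax_full")),
             roots = list(root))
}

make_twoDPN <- function(leg = 12, channel_w = 2, pad_w = 8, pad_h = 6) {
  src <- pad_node("source", rect_shape(pad_w, pad_h, rot = 0, role = "cut"),
                  layer = 1, children = list(
    pad_node("leg1", rect_shape("leg", channel_w, role = "cut"),
             placement(angle = 270, attach = "abut"), children = list(
      pad_node("leg2", rect_shape("leg", channel_w * 1.5, role = "cut"),
               placement(angle = 270, attach = "abut"), children = list(
        pad_node("detect", circle_shape(5, role = "cut"),
                 # overlap the channel end by 1 mm: a cut piece must be one
                 # connected region, tangency would fall apart at the blade
                 placement(angle = 270, dist = "leg+1.5"))))))))
  sink <- pad_node("absorbent", rect_shape(pad_w * 1.5, pad_h, rot = 0,
                                           role = "cut"),
                   placement(angle = 270, dist = 3 * leg), layer = 1)
  pad_design("twoDPN",
             params = list(leg = leg),
             layers = list(pad_layer(1, "membrane", "cut")),
             roots = list(src, sink))
}

make_immunoassay3D <- function(lat = 10, zone_d = 4, channel_w = 2,
                               vent_d = 2) {
  layers <- lapply(1:10, function(i) {
    mat <- if (i %% 2 == 0) "adhesive" else if (i == 5) "membrane" else "paper"
    pad_layer(i, mat, if (mat == "adhesive") "cut" else "wax_buffered")
  })
  stack_ids <- c("sample", "conjugate", "capture", "transfer", "readout")
  tip <- pad_node("vent", circle_shape(vent_d), placement(), layer = 10)
  lateral <- pad_node("lateral", rect_shape("lat", channel_w),
                      placement(angle = 0, attach = "abut"),
                      children = list(
    pad_node("terminal", circle_shape(zone_d),
             placement(angle = 0, attach = "abut"),
             children = list(tip))))
  nd <- pad_node(stack_ids[5], circle_shape(zone_d), placement(), layer = 9,
                 children = list(lateral))
  for (k in 4:1)
    nd <- pad_node(stack_ids[k], circle_shape(zone_d), placement(),
                   layer = 2L * k - 1L, children = list(nd))
  pad_design("immunoassay3D",
             params = list(lat = lat),
             layers = layers, roots = list(nd))
}

#' @rdname make_case_study
#' @param samples number of sample inlets (>= 1).
#' @param plan ordered fan-outs of the split stages; each in `{2, 3, 4}`.
#' @param zone_d zone diameter mm; `channel_w` channel width mm;
#'   `channel_len` per-stage channel lengths (recycled); `pitch` inlet
#'   spacing mm.
#' @export
make_splitter3D <- function(samples = 4, plan = c(2, 2, 4), zone_d = 3,
                            channel_w = 1, channel_len = NULL, pitch = 40) {
  stopifnot(samples >= 1, all(plan %in% 2:4))
  K <- length(plan)
  if (is.null(channel_len)) channel_len <- pmax(8 - 2 * (seq_len(K) - 1), 3)
  channel_len <- rep_len(channel_len, K)
  params <- stats::setNames(as.list(channel_len), paste0("len", seq_len(K)))
  layers <- lapply(seq_len(2 * K + 3), function(i)
    pad_layer(i, if (i %% 2 == 0) "adhesive" else "paper",
              if (i %% 2 == 0) "cut" else "wax_buffered"))

  fan_angles <- function(f) switch(as.character(f),
    "2" = c(240, 300), "3" = c(230, 270, 310),
    "4" = c(225, 255, 285, 315))

  # split unit at stage k (paper layer 2k+1): inlet + f channels + f outlet
  # zones; each outlet feeds the next stage (or a terminal test zone) two
  # layers down, through an auto-generated adhesive hole
  unit <- function(prefix, k) {
    layer_in <- 2L * k + 1L
    if (k > K) # terminal test zone on the last paper layer
      return(pad_node(paste0(prefix, "_t"), circle_shape(zone_d),
                      placement(), layer = layer_in))
    f <- plan[k]
    chans <- lapply(seq_len(f), function(j) {
      a <- fan_angles(f)[j]
      pad_node(paste0(prefix, "_c", j),
               rect_shape(paste0("len", k), channel_w),
               placement(angle = a, attach = "abut"),
               children = list(
        pad_node(paste0(prefix, "_o", j), circle_shape(zone_d),
                 placement(angle = a, attach = "abut"),
                 children = list(unit(paste0(prefix, "_o", j), k + 1L)))))
    })
    pad_node(paste0(prefix, "_in"), circle_shape(zone_d), placement(),
             layer = layer_in, children = chans)
  }

  roots <- lapply(seq_len(samples), function(i) {
    first <- unit(paste0("s", i), 1L)
    first$placement <- placement()
    pad_node(paste0("s", i), circle_shape(zone_d),
             placement(angle = 0, dist = (i - 1) * pitch),
             layer = 1, children = list(first))
  })
  pad_design("splitter3D", params = params, layers = layers, roots = roots,
             sheet = sheet_spec(in_mm(8.5), in_mm(11)))
}

make_origami <- function(panel = 20, zone_d = 5, channel_w = 1.5) {
  cross <- function(id, layer) {
    arms <- lapply(1:4, function(j) {
      a <- c(0, 90, 180, 270)[j]
      pad_node(sprintf("%s_a%d", id, j), rect_shape(panel / 3, channel_w),
               placement(angle = a, attach = "abut"))
    })
    pad_node(id, circle_shape(zone_d), placement(), layer = layer,
             children = arms)
  }
  corner <- function(id, layer) {
    dots <- lapply(1:4, function(j) {
      a <- c(45, 135, 225, 315)[j]
      pad_node(sprintf("%s_d%d", id, j), circle_shape(zone_d * 0.6),
               placement(angle = a, dist = panel / 3))
    })
    pad_node(id, circle_shape(zone_d * 0.5), placement(), layer = layer,
             children = dots)
  }
  big <- function(id, layer) {
    pad_node(id, circle_shape(zone_d * 2),
             placement(angle = 45, dist = panel / 8), layer = layer)
  }
  design <- pad_design("origami",
    layers = list(pad_layer(1, "paper", "wax_buffered"),
                  pad_layer(2, "paper", "wax_buffered"),
                  pad_layer(3, "paper", "wax_buffered")),
    roots = list(cross("hub", 1), corner("corners", 2), big("pool", 3)))
  design
}

#' Fold-sheet grid for the origami fixture
#'
#' The 3 x 3 combined-layer grid that completes the origami fold sheet
#' from only the three unique layer designs: row 1 places layers 1-3
#' as designed, row 2 reuses them rotated 180 degrees (the fold flips the
#' panel), row 3 repeats row 1's orientation.
#'
#' @return List of [tile_transform()]s for [combine_layers()].
#' @export
origami_grid <- function() {
  grid <- list()
  for (r in 1:3) for (c in 1:3)
    grid[[length(grid) + 1L]] <-
      tile_transform(r, c, layer = c, rot = if (r == 2) 180 else 0)
  grid
}

#' Miniature three-layer refactoring demonstrator
#'
#' A small three-layer device: a central sample-application zone on layer
#' 1 feeds three circular zones positioned at a distance `L` through three
#' rectangular channels; each zone feeds a splitting channel on layer 2
#' whose two ends drop to test zones on layer 3 — six terminal outputs in
#' all. Because every element is placed relative to its parent, moving one
#' layer-1 zone out to `2 L` is a single edit
#' (`refactor_design(d, nodes = list(arm1 = list(len = "2*L")))`) and the
#' zone's whole cross-layer subtree follows automatically.
#'
#' @param L arm length parameter in mm (> 0).
#' @return A validated [pad_design()].
#' @export
make_figure2_device <- function(L = 12) {
  stopifnot(L > 0)
  arm <- function(i) {
    a <- c(90, 210, 330)[i]
    ends <- lapply(1:2, function(j) {
      ea <- (a + c(90, 270)[j]) %% 360
      pad_node(sprintf("end%d%s", i, letters[j]), circle_shape(3),
               placement(angle = ea, attach = "abut"),
               children = list(
        pad_node(sprintf("out%d%s", i, letters[j]), circle_shape(3),
                 placement(), layer = 3)))
    })
    pad_node(paste0("arm", i), rect_shape("L", 1.2),
             placement(angle = a, attach = "abut"),
             children = list(
      pad_node(paste0("zone", i), circle_shape(4),
               placement(angle = a, attach = "abut"),
               children = list(
        pad_node(paste0("split", i), rect_shape(10, 1.2, rot = (a + 90) %% 360),
                 placement(), layer = 2, children = ends)))))
  }
  pad_design("fig2mini",
             params = list(L = L),
             layers = list(pad_layer(1, "paper", "wax_buffered"),
                           pad_layer(2, "paper", "wax_buffered"),
                           pad_layer(3, "paper", "wax_buffered")),
             roots = list(pad_node("center", circle_shape(6), layer = 1,
                                   children = list(arm(1), arm(2), arm(3)))))
}
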