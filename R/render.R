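# Raster previews / print masks. Masks are binary by construction: drawing
# happens on a cairo png device with antialiasing disabled, in user
# coordinates that are physical millimetres, so pixel dimensions follow
# directly from physical extent and dpi.

#' Canvas rectangle enclosing a whole design
#'
#' One canvas is shared by all layers of a device so that per-layer masks
#' stay co-registered: the bounding box of every resolved footprint on
#' every layer, grown by a margin.
#'
#' @param resolved a [resolve_design()] result.
#' @param margin margin in mm added on all sides (default: the buffered
#'   border width + 1 mm so borders never clip).
#' @param border border width used for the default margin.
#' @return `c(x0, y0, x1, y1)` in mm.
#' @export
design_canvas <- function(resolved, margin = NULL, border = 1.5) {
  if (is.null(margin)) margin <- border + 1
  resolved_bbox(resolved, margin = margin)
}

#' Render one layer to a binary raster mask
#'
#' Renders a layer at a physical resolution: pixel dimensions are the
#' canvas extent times dpi, rounded up. Wax modes paint the wax region
#' black on white stock and leave flow regions untouched; `cut` mode
#' strokes outline paths only. Text labels (decor role) are drawn in black
#' using R's built-in Hershey vector fonts, so output does not depend on
#' the fonts installed on a particular machine. Antialiasing is off: every
#' pixel is pure black or pure white.
#'
#' @param design a [pad_design()] (or a pre-computed [resolve_design()]
#'   result, in which case `layers_meta` must describe the layers).
#' @param layer layer index to render.
#' @param mode render mode override; `NULL` uses the layer's declared mode.
#' @param dpi raster resolution, dots per inch.
#' @param canvas canvas rectangle `c(x0, y0, x1, y1)` mm; `NULL` computes
#'   [design_canvas()] over the whole design.
#' @param file output PNG path; `NULL` renders to a temporary file.
#' @param include_text draw decor text nodes?
#' @return Object of class `pad_raster`: list with `mask` (logical matrix,
#'   `TRUE` = white, rows top to bottom), `px` (width, height), `canvas`,
#'   `dpi`, `mode`, `file`.
#' @export
render_layer <- function(design, layer, mode = NULL, dpi = 600,
                         canvas = NULL, file = NULL, include_text = TRUE) {
  lyr <- layer_lookup(design)[[as.character(layer)]]
  if (is.null(lyr)) stop("unknown layer ", layer, call. = FALSE)
  if (is.null(mode)) mode <- lyr$mode
  resolved <- resolve_design(design)
  border <- design$defaults$border
  if (is.null(canvas)) canvas <- design_canvas(resolved, border = border)

  px_w <- as.integer(ceiling((canvas[3] - canvas[1]) / 25.4 * dpi))
  px_h <- as.integer(ceiling((canvas[4] - canvas[2]) / 25.4 * dpi))
  if (is.null(file)) file <- tempfile(fileext = ".png")

  grDevices::png(file, width = px_w, height = px_h, type = "cairo",
                 antialias = "none")
  ok <- FALSE
  tryCatch({
    draw_layer(resolved, design, layer, mode, canvas,
               px = c(px_w, px_h), include_text = include_text)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("rendering failed", call. = FALSE)

  img <- png::readPNG(file)
  gray <- if (length(dim(img)) == 3L) img[, , 1] else img
  structure(list(mask = gray > 0.5, px = c(px_w, px_h), canvas = canvas,
                 dpi = dpi, mode = mode, file = file),
            class = "pad_raster")
}

#' @export
print.pad_raster <- function(x, ...) {
  cat("<pad_raster> ", x$px[1], "x", x$px[2], " px @ ", x$dpi, " dpi, mode ",
      x$mode, ", ", round(100 * mean(!x$mask), 1), "% inked\n", sep = "")
  invisible(x)
}

# draw one layer into the currently open device, user coords = mm
draw_layer <- function(resolved, design, layer, mode, canvas, px = NULL,
                       include_text = TRUE, origin = c(0, 0)) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  # when rendering a full-device raster the window is the canvas; when
  # drawing a tile into a larger sheet the caller sets the window itself
  if (!is.null(px))
    graphics::plot.window(xlim = canvas[c(1, 3)], ylim = canvas[c(2, 4)])
  draw_layer_content(resolved, design, layer, mode, canvas, include_text,
                     origin)
}

draw_layer_content <- function(resolved, design, layer, mode, canvas,
                               include_text = TRUE, origin = c(0, 0)) {
  border <- design$defaults$border
  stroke <- design$defaults$cut_stroke
  if (identical(mode, "cut")) {
    groups <- flow_components(resolved, layer, role = "cut")
    if (!length(groups)) groups <- flow_components(resolved, layer)
    for (g in groups) {
      cp <- cut_outline(g, stroke)
      for (r in cp$rings)
        graphics::polypath(r$x + origin[1], r$y + origin[2], border = "black",
                           col = NA, lwd = max(1, stroke / 25.4 * 96))
    }
  } else {
    region <- wax_region(resolved, layer, mode, canvas, border)
    if (length(region)) {
      xs <- unlist(lapply(region, function(r) c(r$x + origin[1], NA)))
      ys <- unlist(lapply(region, function(r) c(r$y + origin[2], NA)))
      graphics::polypath(xs[-length(xs)], ys[-length(ys)],
                         col = "black", border = NA, rule = "evenodd")
    }
  }
  if (include_text) {
    # in full-field mode the background is solid ink, so labels are knocked
    # out white; in buffered/cut modes they print black
    txt_col <- if (identical(mode, "wax_full")) "white" else "black"
    for (el in resolved) {
      if (el$layer != layer || el$kind != "text") next
      sh <- element_text_spec(el, design)
      graphics::text(el$x + origin[1], el$y + origin[2], labels = sh$string,
                     srt = sh$rotation, col = txt_col,
                     vfont = c("sans serif", "bold"),
                     cex = sh$height / hershey_cap_height())
    }
  }
}

# text properties travel on the design tree, not on resolved elements;
# fetch them back by id
element_text_spec <- function(el, design) {
  spec <- NULL
  walk_nodes(design$roots, function(nd, d) {
    if (identical(nd$id, el$id)) spec <<- nd$shape
  })
  list(string = spec$string,
       height = num_field(spec$height, design$params),
       rotation = num_field(spec$rotation, design$params))
}

# cap height (user units, mm here) of Hershey sans-serif at cex = 1 on the
# open device; cached per device size via strheight
hershey_cap_height <- function() {
  graphics::strheight("X", vfont = c("sans serif", "bold"), cex = 1)
}

#' Write per-layer mask PNGs for a design
#'
#' @param design a [pad_design()].
#' @param dir output directory (created if needed).
#' @param dpi raster resolution.
#' @param mode render-mode override for all layers; `NULL` keeps each
#'   layer's declared mode.
#' @return Named character vector of written files (by layer index).
#' @export
write_layer_masks <- function(design, dir, dpi = 600, mode = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- sort(vapply(design$layers, `[[`, integer(1), "index"))
  files <- character(0)
  for (i in idx) {
    f <- file.path(dir, sprintf("%s_layer%02d.png", design$name, i))
    render_layer(design, i, mode = mode, dpi = dpi, file = f)
    files[[as.character(i)]] <- f
  }
  files
}
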