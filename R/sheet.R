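#' Physical sheet specification for page tiling
#'
#' Describes the printable page onto which intact layer designs are tiled
#' as many times as space allows, so that a printed sheet yields many
#' devices at exactly the intended physical size.
#'
#' @param width,height page size in mm (use `in_mm()` for inch pages;
#'   8.5 x 11 in is `in_mm(8.5)` x `in_mm(11)` = 215.9 x 279.4 mm).
#' @param margin page margin in mm (all four sides), >= 0.
#' @param spacing spacing between adjacent tiles in mm, >= 0.
#' @param dpi raster resolution used for any raster output.
#' @param order tiling order; only `"row_major"` (left-to-right,
#'   top-to-bottom) is defined.
#' @return An object of class `pad_sheet`.
#' @export
sheet_spec <- function(width, height, margin = 5, spacing = 2, dpi = 600,
                       order = "row_major") {
  stopifnot(width > 0, height > 0, margin >= 0, spacing >= 0, dpi > 0)
  structure(list(width = width, height = height, margin = margin,
                 spacing = spacing, dpi = dpi,
                 order = match.arg(order, "row_major")),
            class = "pad_sheet")
}

#' Inches to millimetres
#'
#' Exact conversion at 25.4 mm per inch.
#' @param x inches.
#' @return millimetres.
#' @export
in_mm <- function(x) x * 25.4

#' Row-major tile layout of a device on a page
#'
#' With page width `W`, margin `m`, spacing `s` and device width `w`, the
#' number of columns is `floor((W - 2m + s) / (w + s))` and rows
#' analogously; leftover space is left at the right and bottom. Every
#' tile's bounding box is guaranteed to lie within the printable area.
#'
#' @param device_wh device bounding-box width and height, mm.
#' @param sheet a [sheet_spec()].
#' @return List with `n_cols`, `n_rows`, `n_tiles` and `origins`, an
#'   `n_tiles` x 2 matrix of tile top-left corners in page mm (origin at
#'   the page's bottom-left, y up).
#' @section Errors: device larger than the printable area.
#' @export
tile_layout <- function(device_wh, sheet) {
  w <- device_wh[1]; h <- device_wh[2]
  pw <- sheet$width - 2 * sheet$margin
  ph <- sheet$height - 2 * sheet$margin
  if (w > pw || h > ph)
    stop(sprintf("device (%.6g x %.6g mm) exceeds printable area (%.6g x %.6g mm)",
                 w, h, pw, ph), call. = FALSE)
  n_cols <- floor((pw + sheet$spacing) / (w + sheet$spacing))
  n_rows <- floor((ph + sheet$spacing) / (h + sheet$spacing))
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  origins <- cbind(
    x = sheet$margin + (grid$col - 1) * (w + sheet$spacing),
    y = sheet$height - sheet$margin - (grid$row - 1) * (h + sheet$spacing))
  list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
       n_tiles = as.integer(n_cols * n_rows), origins = origins)
}

#' Tile a design onto physically-dimensioned PDF sheets
#'
#' Writes a PDF with one page per layer, each page exactly
#' `sheet$width` x `sheet$height` mm (an image alone carries no dimensional
#' data — embedding the page size is what makes prints dimensionally
#' exact). On each page the layer is repeated row-major as many times as
#' the printable area allows, so one printed sheet supplies material for
#' many devices.
#'
#' @param design a [pad_design()].
#' @param sheet a [sheet_spec()]; `NULL` uses the design's `sheet` block or
#'   a letter-size default.
#' @param file output PDF path.
#' @param mode render-mode override for all layers.
#' @return Invisibly, a list with `file`, `pages`, `tiles_per_page`,
#'   `layout`, and `device_wh`.
#' @export
tile_sheet <- function(design, sheet = NULL, file, mode = NULL) {
  if (is.null(sheet)) sheet <- design$sheet
  if (is.null(sheet)) sheet <- sheet_spec(in_mm(8.5), in_mm(11))
  resolved <- resolve_design(design)
  canvas <- design_canvas(resolved, border = design$defaults$border)
  wh <- c(canvas[3] - canvas[1], canvas[4] - canvas[2])
  lay <- tile_layout(wh, sheet)
  idx <- sort(vapply(design$layers, `[[`, integer(1), "index"))

  grDevices::pdf(file, width = sheet$width / 25.4, height = sheet$height / 25.4,
                 paper = "special", onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (i in idx) {
    m <- if (is.null(mode)) layer_lookup(design)[[as.character(i)]]$mode
         else mode
    op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, sheet$width), ylim = c(0, sheet$height))
    for (t in seq_len(lay$n_tiles)) {
      # tile origin is its top-left corner; content coords are canvas mm
      off <- c(lay$origins[t, 1] - canvas[1],
               lay$origins[t, 2] - wh[2] - canvas[2])
      draw_layer_content(resolved, design, i, m, canvas, origin = off)
    }
    graphics::par(op)
  }
  invisible(list(file = file, pages = length(idx),
                 tiles_per_page = lay$n_tiles, layout = lay, device_wh = wh))
}

#' Read the page sizes recorded in a PDF file
#'
#' Scans a PDF for `/MediaBox` entries and returns the page dimensions in
#' millimetres (a metadata check that printed output will be dimensionally
#' exact; PDF records box sizes in points, 72 per inch).
#'
#' @param file PDF path.
#' @return A matrix with columns `width`, `height` (mm), one row per
#'   distinct MediaBox occurrence.
#' @export
pdf_page_sizes <- function(file) {
  lines <- readLines(file, warn = FALSE, skipNul = TRUE)
  m <- gregexpr("/MediaBox\\s*\\[([-0-9. ]+)\\]", lines, useBytes = TRUE)
  hits <- unlist(regmatches(lines, m))
  if (!length(hits)) stop("no /MediaBox found in ", file, call. = FALSE)
  sizes <- t(vapply(hits, function(h) {
    nums <- as.numeric(strsplit(trimws(sub(".*\\[", "", sub("\\]", "", h))),
                                "\\s+")[[1]])
    c(width = (nums[3] - nums[1]) / 72 * 25.4,
      height = (nums[4] - nums[2]) / 72 * 25.4)
  }, numeric(2)))
  rownames(sizes) <- NULL
  sizes
}

# ---- origami combined layers -----------------------------------------------

#' Tile transform for origami fold sheets
#'
#' One cell of a combined-layer grid: which source layer to place at grid
#' position (row, col), reflected and/or rotated. Reflection is applied
#' before rotation; both are isometries, so within-tile distances are
#' preserved exactly.
#'
#' @param row,col 1-based grid position (rows run downward on the sheet).
#' @param layer source layer index to reuse.
#' @param rot rotation in degrees, one of 0, 90, 180, 270.
#' @param flip reflection: `"none"`, `"x"` (across the x axis) or `"y"`.
#' @return An object of class `pad_tile`.
#' @export
tile_transform <- function(row, col, layer, rot = 0, flip = "none") {
  stopifnot(rot %in% c(0, 90, 180, 270))
  flip <- match.arg(flip, c("none", "x", "y"))
  structure(list(row = as.integer(row), col = as.integer(col),
                 layer = as.integer(layer), rot = rot, flip = flip),
            class = "pad_tile")
}

apply_isometry <- function(pts, rot, flip, center = c(0, 0)) {
  p <- sweep(pts, 2, center)
  if (flip == "x") p[, 2] <- -p[, 2]
  if (flip == "y") p[, 1] <- -p[, 1]
  p <- p %*% t(rot_mat(rot))
  sweep(p, 2, center, "+")
}

#' Combine transformed layer copies into one origami fold sheet
#'
#' Origami devices are folded from a single patterned sheet, so their
#' layout is a grid of layer designs, many of which are the same design
#' reused under rotation or reflection rather than drawn again. This maps
#' each grid cell's source-layer elements by the cell's isometry
#' (reflection, then rotation, about the source canvas centre) into the
#' cell, producing a single synthetic combined layer.
#'
#' @param design a [pad_design()].
#' @param grid list of [tile_transform()]s.
#' @param cell cell width/height `c(w, h)` in mm; `NULL` uses the design
#'   canvas extent (all cells uniform). It is an error for a source layer's
#'   extent to exceed the cell.
#' @return A `pad_resolved` element list for the combined layer: ids are
#'   `<source id>@<row>,<col>`, `layer` is 0 (synthetic), with `tile`
#'   (row, col) and `source_layer` fields added.
#' @export
combine_layers <- function(design, grid, cell = NULL) {
  resolved <- resolve_design(design)
  canvas <- design_canvas(resolved, border = design$defaults$border)
  src_wh <- c(canvas[3] - canvas[1], canvas[4] - canvas[2])
  if (is.null(cell)) cell <- src_wh
  if (src_wh[1] > cell[1] + 1e-9 || src_wh[2] > cell[2] + 1e-9)
    stop("grid cell is smaller than the source layer extent", call. = FALSE)
  declared <- vapply(design$layers, `[[`, integer(1), "index")
  c0 <- c((canvas[1] + canvas[3]) / 2, (canvas[2] + canvas[4]) / 2)

  out <- list()
  for (tt in grid) {
    if (!tt$layer %in% declared)
      stop("tile references undeclared layer ", tt$layer, call. = FALSE)
    # rows run downward: row 1 at the top of the sheet
    cc <- c((tt$col - 0.5) * cell[1], -(tt$row - 0.5) * cell[2])
    for (el in resolved) {
      if (el$layer != tt$layer) next
      fp <- apply_isometry(el$footprint, tt$rot, tt$flip, c0)
      ctr <- apply_isometry(rbind(c(el$x, el$y)), tt$rot, tt$flip, c0)
      shift <- cc - c0
      el$footprint <- sweep(fp, 2, shift, "+")
      el$x <- ctr[1] + shift[1]; el$y <- ctr[2] + shift[2]
      el$source_layer <- el$layer
      el$layer <- 0L
      el$tile <- c(tt$row, tt$col)
      el$id <- sprintf("%s@%d,%d", el$id, tt$row, tt$col)
      out[[el$id]] <- el
    }
  }
  structure(out, class = "pad_resolved")
}
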