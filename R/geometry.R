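# Planar geometry services on resolved footprints. Polygon booleans and
# offsets are delegated to polyclip (the Clipper library); regions are
# polyclip-style lists of rings, each ring a list(x, y), with outer rings
# counter-clockwise and holes clockwise.

fp_to_ring <- function(fp) list(x = fp[, 1], y = fp[, 2])

ring_to_mat <- function(r) cbind(r$x, r$y)

#' Ring and region measures
#'
#' `ring_area()` is the signed shoelace area of one ring (positive =
#' counter-clockwise). `region_area()` sums signed ring areas, so holes
#' subtract. `ring_length()` and `region_perimeter()` measure closed-ring
#' boundary length.
#'
#' @param ring a `list(x, y)` ring.
#' @param region a list of rings.
#' @return Area in mm^2 / length in mm.
#' @name measures
NULL

#' @rdname measures
#' @export
ring_area <- function(ring) {
  x <- ring$x; y <- ring$y
  j <- c(seq_along(x)[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' @rdname measures
#' @export
region_area <- function(region) sum(vapply(region, ring_area, numeric(1)))

#' @rdname measures
#' @export
ring_length <- function(ring) {
  x <- ring$x; y <- ring$y
  j <- c(seq_along(x)[-1], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' @rdname measures
#' @export
region_perimeter <- function(region) sum(vapply(region, ring_length, numeric(1)))

# polyclip with a fixed absolute resolution so results do not depend on the
# coordinate magnitudes of a particular device (1e-9 mm grid)
pc_op <- function(A, B, op) {
  polyclip::polyclip(A, B, op = op, x0 = 0, y0 = 0, eps = 1e-9)
}

region_union <- function(regions) {
  regions <- Filter(length, regions)
  if (!length(regions)) return(list())
  acc <- regions[[1]]
  for (r in regions[-1]) acc <- pc_op(acc, r, "union")
  if (length(regions) == 1L) acc <- pc_op(acc, list(), "union")
  acc
}

# do two footprints overlap or touch (within tol)? Touching pairs must count
# as connected: an abutting channel/zone pair is one hydrophilic path.
polygons_touch <- function(a, b, tol = 1e-6) {
  # cheap bbox rejection first
  if (min(a[, 1]) > max(b[, 1]) + tol || min(b[, 1]) > max(a[, 1]) + tol ||
      min(a[, 2]) > max(b[, 2]) + tol || min(b[, 2]) > max(a[, 2]) + tol)
    return(FALSE)
  A <- polyclip::polyoffset(list(fp_to_ring(a)), tol,
                            jointype = "miter", miterlim = 10)
  length(pc_op(A, list(fp_to_ring(b)), "intersection")) > 0
}

#' Group flow shapes into connected components
#'
#' Partitions the flow-role elements of one layer into hydrophilic
#' networks: two elements share a group iff their footprints intersect or
#' touch, transitively. Touching (zero-area contact, as produced by
#' abut-attached channels) counts as connected, within a small tolerance.
#' Each group carries the polygon union of its members' footprints —
#' the substrate for snap-to-shape buffering and cut outlines.
#'
#' @param resolved a [resolve_design()] result (or any list of elements).
#' @param layer layer index to group; `NULL` uses all elements in
#'   `resolved` regardless of layer.
#' @param role which role participates (default `"flow"`; cut layers group
#'   their `"cut"` pieces the same way).
#' @param tol contact tolerance in mm.
#' @return List of groups, each `list(ids, footprint)` where `footprint`
#'   is a region (list of rings).
#' @export
flow_components <- function(resolved, layer = NULL, role = "flow",
                            tol = 1e-6) {
  els <- Filter(function(e) identical(e$role, role) &&
                  (is.null(layer) || e$layer == layer), resolved)
  n <- length(els)
  if (n == 0L) return(list())
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (polygons_touch(els[[i]]$footprint, els[[j]]$footprint, tol))
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) {
    members <- els[comp == k]
    list(ids = vapply(members, `[[`, character(1), "id"),
         footprint = region_union(lapply(members, function(e)
           list(fp_to_ring(e$footprint)))))
  })
}

#' Shape-fitting ("snap-to-shape") wax border
#'
#' Computes the buffered-mode wax region for one flow group: a ring of
#' constant width hugging the union of the group's footprints,
#' `(union (+) borderWidth) \\ union`. The border never crosses the
#' interior, so a continuous channel network is never broken, and because
#' only a ring is inked this mode uses less wax than flooding the whole
#' background.
#'
#' @param group a group from [flow_components()], or a region (list of
#'   rings), or a single footprint matrix.
#' @param border border width in mm (> 0).
#' @return The wax region as a list of rings (outer boundary + hole
#'   tracing the flow union).
#' @export
fitted_border <- function(group, border = 1.5) {
  stopifnot(border > 0)
  region <- as_region(group)
  if (!length(region)) stop("degenerate (empty) flow union", call. = FALSE)
  grown <- polyclip::polyoffset(region, border, jointype = "round")
  pc_op(grown, region, "minus")
}

#' Full-field wax mask
#'
#' The classic wax-printing mask: the whole canvas is inked except the
#' hydrophilic flow network, i.e. canvas minus the union of flow
#' footprints ("white channels upon a black background").
#'
#' @param resolved a [resolve_design()] result (or element list).
#' @param canvas `c(x0, y0, x1, y1)` rectangle in mm.
#' @param layer layer index (`NULL` = all elements present).
#' @return The wax region as a list of rings.
#' @export
full_field <- function(resolved, canvas, layer = NULL) {
  els <- Filter(function(e) identical(e$role, "flow") &&
                  (is.null(layer) || e$layer == layer), resolved)
  canv <- list(list(x = canvas[c(1, 3, 3, 1)], y = canvas[c(2, 2, 4, 4)]))
  for (e in els) {
    fp <- e$footprint
    if (min(fp[, 1]) < canvas[1] || max(fp[, 1]) > canvas[3] ||
        min(fp[, 2]) < canvas[2] || max(fp[, 2]) > canvas[4])
      stop("footprint of '", e$id, "' lies outside the canvas", call. = FALSE)
  }
  if (!length(els)) return(canv)
  un <- region_union(lapply(els, function(e) list(fp_to_ring(e$footprint))))
  pc_op(canv, un, "minus")
}

#' Cut outline path for plotters
#'
#' Traces the boundary of a flow group's union as closed rings with a
#' nominal stroke width — the path a knife plotter or laser cutter follows
#' to cut the piece out of paper, membrane, or adhesive film. Outer rings
#' are counter-clockwise, interior holes clockwise.
#'
#' @param group a group from [flow_components()], a region, or a footprint
#'   matrix.
#' @param stroke stroke width in mm (> 0), nominal (plotters cut a line).
#' @return Object of class `pad_cutpath`: `list(rings, stroke)`; the total
#'   path length is `region_perimeter(rings)`.
#' @export
cut_outline <- function(group, stroke = 0.2) {
  stopifnot(stroke > 0)
  rings <- as_region(group)
  structure(list(rings = rings, stroke = stroke), class = "pad_cutpath")
}

#' @export
print.pad_cutpath <- function(x, ...) {
  cat("<pad_cutpath> ", length(x$rings), " ring(s), path length ",
      format(region_perimeter(x$rings), digits = 6), " mm, stroke ",
      format(x$stroke), " mm\n", sep = "")
  invisible(x)
}

as_region <- function(x) {
  if (is.matrix(x)) return(region_union(list(list(fp_to_ring(x)))))
  if (is.list(x) && !is.null(x$footprint)) return(x$footprint)
  if (is.list(x) && length(x) && !is.null(x[[1]]$x)) return(x)
  if (is.list(x) && !length(x)) return(list())
  stop("cannot interpret as a region", call. = FALSE)
}

#' Layer wax region in a given render mode
#'
#' The region of a layer that receives wax ink: in `wax_full` mode the
#' canvas minus the flow union; in `wax_buffered` mode the merged
#' snap-to-shape borders of all flow groups (clipped to the canvas). Both
#' modes leave exactly the same white flow area — only background coverage
#' differs, with buffered wax area never exceeding full-field wax area.
#'
#' @param resolved a [resolve_design()] result.
#' @param layer layer index.
#' @param mode `"wax_full"` or `"wax_buffered"`.
#' @param canvas `c(x0, y0, x1, y1)` in mm.
#' @param border buffered border width in mm.
#' @return Wax region as a list of rings.
#' @export
wax_region <- function(resolved, layer, mode, canvas, border = 1.5) {
  if (identical(mode, "wax_full"))
    return(full_field(resolved, canvas, layer))
  groups <- flow_components(resolved, layer)
  if (!length(groups)) return(list())
  rings <- region_union(lapply(groups, fitted_border, border = border))
  canv <- list(list(x = canvas[c(1, 3, 3, 1)], y = canvas[c(2, 2, 4, 4)]))
  pc_op(rings, canv, "intersection")
}

#' Export cut paths as SVG
#'
#' Writes stroke-only SVG paths (no fill) sized in physical millimetres,
#' suitable for import into knife-plotter and laser-cutter software.
#'
#' @param cutpaths a `pad_cutpath` or list of them.
#' @param path output file.
#' @param bbox optional `c(x0, y0, x1, y1)` canvas; default fits content.
#' @return `path`, invisibly.
#' @export
cutpaths_to_svg <- function(cutpaths, path, bbox = NULL) {
  if (inherits(cutpaths, "pad_cutpath")) cutpaths <- list(cutpaths)
  all_rings <- unlist(lapply(cutpaths, `[[`, "rings"), recursive = FALSE)
  if (is.null(bbox)) {
    xs <- unlist(lapply(all_rings, `[[`, "x"))
    ys <- unlist(lapply(all_rings, `[[`, "y"))
    bbox <- c(min(xs) - 1, min(ys) - 1, max(xs) + 1, max(ys) + 1)
  }
  w <- bbox[3] - bbox[1]; h <- bbox[4] - bbox[2]
  out <- sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%smm" height="%smm" ',
    'viewBox="0 0 %s %s">'), fmt_num(w), fmt_num(h), fmt_num(w), fmt_num(h))
  for (cp in cutpaths) {
    for (r in cp$rings) {
      d <- paste0("M ", paste(fmt_num(r$x - bbox[1]), fmt_num(bbox[4] - r$y),
                              collapse = " L "), " Z")
      out <- c(out, sprintf(
        '<path d="%s" fill="none" stroke="black" stroke-width="%s"/>',
        d, fmt_num(cp$stroke)))
    }
  }
  writeLines(c(out, "</svg>"), path)
  invisible(path)
}
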