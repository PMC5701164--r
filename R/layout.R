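#' Resolve a design to absolute per-layer geometry
#'
#' Walks the node forest and turns every relatively-placed node into a
#' `ResolvedElement` with an absolute anchor position and absolute
#' footprint polygon on its layer. Placement semantics:
#' \itemize{
#'   \item a root's placement is relative to the global origin, so a
#'     single root with distance 0 sits at (0, 0);
#'   \item `attach = "center"`: child anchor = parent anchor +
#'     `dist * (cos angle, sin angle)`;
#'   \item `attach = "abut"`: the child is pushed out along `angle` until
#'     its near boundary touches the parent's boundary (the parent's
#'     support extent along `angle` plus the child's along the opposite
#'     direction), plus `dist` of clearance. Rectangles attached this way
#'     lie lengthwise along `angle` with anchor on the near edge, so
#'     lengthening a channel extends its far end without displacing the
#'     channel's own anchor — exactly how an edit propagates to
#'     descendants but not to the edited channel itself;
#'   \item a cross-layer child with distance 0 lands exactly on its
#'     parent's anchor: the multi-layer alignment guarantee is exact, not
#'     approximate.
#' }
#' Children are resolved in declaration order; auto-generated adhesive
#' holes (see [auto_holes()]) are inserted first so they appear as ordinary
#' elements. Distance expressions are evaluated here against the design's
#' parameters.
#'
#' @param design a valid [pad_design()].
#' @return An object of class `pad_resolved`: a named list (by node id) of
#'   elements, each a list with `id`, `layer`, `material`, `x`, `y` (anchor,
#'   mm), `role`, `kind`, `auto` (auto-generated hole?), `parent`,
#'   `parent_layer`, and `footprint` (n x 2 matrix, mm). Use
#'   [resolved_table()] for a flat data.frame view.
#' @export
resolve_design <- function(design) {
  viol <- validate(design)
  if (nrow(viol))
    stop("cannot resolve an invalid design:\n",
         paste(sprintf("  [%s] %s", viol$where, viol$message),
               collapse = "\n"), call. = FALSE)
  design <- auto_holes(design)
  params <- design$params
  out <- list()

  place <- function(nd, parent) {
    angle <- num_field(nd$placement$angle, params) %% 360
    dist <- num_field(nd$placement$dist, params)
    layer <- if (is.na(nd$layer)) parent$layer else nd$layer
    fp <- local_footprint(nd$shape, angle, nd$placement$attach, params)
    u <- unit_vec(angle)
    D <- if (identical(nd$placement$attach, "abut")) {
      pext <- if (is.null(parent$fp)) 0 else support_extent(parent$fp, angle)
      pext + dist + support_extent(fp, (angle + 180) %% 360)
    } else dist
    pos <- c(parent$x, parent$y) + u * D

    el <- list(id = nd$id, layer = layer,
               material = layer_material(design, layer),
               x = pos[1], y = pos[2],
               role = nd$shape$role, kind = nd$shape$kind,
               auto = isTRUE(grepl("__hole$", nd$id)),
               parent = parent$id, parent_layer = parent$layer,
               footprint = sweep(fp, 2, pos, "+"))
    if (!is.null(out[[nd$id]]))
      stop("duplicate node id '", nd$id, "' during resolve", call. = FALSE)
    out[[nd$id]] <<- el
    ctx <- list(id = nd$id, x = pos[1], y = pos[2], layer = layer, fp = fp)
    for (ch in nd$children) place(ch, ctx)
  }

  origin <- list(id = NA_character_, x = 0, y = 0, layer = NA_integer_,
                 fp = NULL)
  for (r in design$roots) place(r, origin)
  structure(out, class = "pad_resolved")
}

#' @export
print.pad_resolved <- function(x, ...) {
  cat("<pad_resolved> ", length(x), " element(s) on ",
      length(unique(vapply(x, `[[`, integer(1), "layer"))), " layer(s)\n",
      sep = "")
  invisible(x)
}

#' Flat table view of resolved geometry
#'
#' @param resolved a [resolve_design()] result.
#' @return A data.frame with one row per element: `id`, `layer`,
#'   `material`, `x`, `y`, `role`, `kind`, `auto`, `parent`.
#' @export
resolved_table <- function(resolved) {
  data.frame(
    id = vapply(resolved, `[[`, character(1), "id"),
    layer = vapply(resolved, `[[`, integer(1), "layer"),
    material = vapply(resolved, `[[`, character(1), "material"),
    x = vapply(resolved, `[[`, numeric(1), "x"),
    y = vapply(resolved, `[[`, numeric(1), "y"),
    role = vapply(resolved, `[[`, character(1), "role"),
    kind = vapply(resolved, `[[`, character(1), "kind"),
    auto = vapply(resolved, `[[`, logical(1), "auto"),
    parent = vapply(resolved, function(e) e$parent %||% NA_character_,
                    character(1)),
    row.names = NULL)
}

#' Edit a design and let the layout refactor itself
#'
#' Applies parameter and per-node property edits and returns the edited
#' design; re-resolving it repositions exactly the edited nodes and their
#' descendants (across layers, auto-holes included) while every other
#' element stays bit-identical — the point of relative placement: a change
#' that would mean manually repositioning dozens of elements in a drawing
#' program is a one-number edit here.
#'
#' @param design a [pad_design()].
#' @param params named list of parameter changes; every name must already
#'   be declared.
#' @param nodes named list (by node id) of property changes. Placement
#'   properties: `angle`, `dist`, `attach`, `layer`; shape properties:
#'   `d`, `len`, `w`, `rot`, `text`, `height`. Values may be numbers or
#'   expression strings.
#' @return The edited design.
#' @export
refactor_design <- function(design, params = list(), nodes = list()) {
  for (p in names(params)) {
    if (!p %in% names(design$params))
      stop("unknown parameter '", p, "'", call. = FALSE)
    design$params[[p]] <- params[[p]]
  }
  placement_props <- c("angle", "dist", "attach", "layer")
  for (id in names(nodes)) {
    found <- new.env(); found$hit <- FALSE
    design$roots <- modify_node(design$roots, id, function(nd) {
      for (k in names(nodes[[id]])) {
        v <- nodes[[id]][[k]]
        if (k %in% placement_props) {
          if (k == "layer") nd$layer <- as.integer(v)
          else nd$placement[[k]] <- v
        } else if (k %in% names(nd$shape) || k %in%
                   c("d", "len", "w", "rot", "text", "height")) {
          key <- if (k == "text") "string" else k
          if (!key %in% names(nd$shape))
            stop("node '", id, "' has no property '", k, "'", call. = FALSE)
          nd$shape[[key]] <- v
        } else stop("unknown property '", k, "'", call. = FALSE)
      }
      nd
    }, found)
    if (!isTRUE(found$hit))
      stop("no node with id '", id, "'", call. = FALSE)
  }
  design
}

#' Diff two resolutions of the same design
#'
#' Compares element anchors between two [resolve_design()] results that
#' share a node-id set and reports which elements moved by more than
#' `tolerance`, partitioned by layer material — the bookkeeping behind
#' "editing one channel repositions N elements downstream". Layout is
#' closed-form, so true motion is many orders of magnitude above float
#' noise and the default tolerance of 1e-6 mm separates them cleanly.
#'
#' @param before,after [resolve_design()] results with identical id sets.
#' @param tolerance displacement below which an element counts as unmoved
#'   (mm).
#' @return An object of class `pad_diff`: list with `moved` (character ids),
#'   `n_moved`, `by_material` (named integer), `by_layer` (named integer),
#'   `displacement` (named numeric, all ids), `tolerance`.
#' @export
diff_positions <- function(before, after, tolerance = 1e-6) {
  ids <- names(before)
  if (!setequal(ids, names(after)))
    stop("designs do not share a node-id set: ",
         paste(union(setdiff(ids, names(after)),
                     setdiff(names(after), ids)), collapse = ", "),
         call. = FALSE)
  disp <- vapply(ids, function(i) {
    sqrt((after[[i]]$x - before[[i]]$x)^2 + (after[[i]]$y - before[[i]]$y)^2)
  }, numeric(1))
  moved <- ids[disp > tolerance]
  mat <- vapply(moved, function(i) before[[i]]$material, character(1))
  lay <- vapply(moved, function(i) before[[i]]$layer, integer(1))
  structure(list(moved = moved, n_moved = length(moved),
                 by_material = c(table(factor(mat,
                   levels = c("paper", "adhesive", "membrane")))),
                 by_layer = c(table(lay)),
                 displacement = disp, tolerance = tolerance),
            class = "pad_diff")
}

#' @export
print.pad_diff <- function(x, ...) {
  cat("<pad_diff> ", x$n_moved, " element(s) moved (tolerance ",
      format(x$tolerance), " mm)\n", sep = "")
  if (x$n_moved) {
    bm <- x$by_material[x$by_material > 0]
    cat("  by material:",
        paste(names(bm), bm, sep = "=", collapse = " "), "\n")
    cat("  by layer:   ",
        paste(names(x$by_layer), x$by_layer, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Count design elements per layer
#'
#' Counts every element the design resolves to — including auto-generated
#' adhesive holes — per layer and in total. This is the element bookkeeping
#' used to reason about how large a manual re-layout would be.
#'
#' @param design a valid [pad_design()].
#' @return List with `per_layer` (named integer vector, names = layer
#'   indices, zero-count layers included) and `total`.
#' @export
count_elements <- function(design) {
  design <- auto_holes(design)
  idx <- vapply(design$layers, `[[`, integer(1), "index")
  counts <- stats::setNames(integer(length(idx)), as.character(sort(idx)))
  count_walk <- function(nodes, parent_layer) {
    for (nd in nodes) {
      layer <- if (is.na(nd$layer)) parent_layer else nd$layer
      key <- as.character(layer)
      if (!is.na(layer) && key %in% names(counts))
        counts[[key]] <<- counts[[key]] + 1L
      count_walk(nd$children, layer)
    }
  }
  count_walk(design$roots, 1L)
  list(per_layer = counts, total = sum(counts))
}

#' Check cross-layer alignment of a resolution
#'
#' Fluid passes between layers only where zones overlap, and in assembled
#' devices those zones must be concentric for reproducible capillary flow.
#' For every parent/child pair on different layers this checks that the
#' anchors coincide to within `tolerance` and the footprints actually
#' overlap; relative placement makes the residual exactly 0 for dist-0
#' connections, so the default tolerance is 0.
#'
#' @param resolved a [resolve_design()] result.
#' @param tolerance maximum allowed centre offset (mm).
#' @return A data.frame of misaligned pairs (`parent`, `child`, `offset`,
#'   `overlap`); zero rows iff all cross-layer connections are aligned.
#' @export
check_alignment <- function(resolved, tolerance = 0) {
  rows <- list()
  for (el in resolved) {
    if (is.na(el$parent) || is.na(el$parent_layer)) next
    if (el$layer == el$parent_layer) next
    pa <- resolved[[el$parent]]
    off <- sqrt((el$x - pa$x)^2 + (el$y - pa$y)^2)
    ov <- polygons_touch(pa$footprint, el$footprint, tol = 1e-9)
    if (off > tolerance || !ov)
      rows[[length(rows) + 1L]] <- data.frame(parent = pa$id, child = el$id,
                                              offset = off, overlap = ov)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(parent = character(0), child = character(0),
                  offset = numeric(0), overlap = logical(0))
}

#' Export resolved geometry as JSON lines
#'
#' One JSON object per element (`id`, `layer`, `material`, `role`, `x`,
#' `y`, `footprint`), a plain machine-readable dump for testing and
#' interchange.
#'
#' @param resolved a [resolve_design()] result.
#' @param path output file; if `NULL`, the lines are returned.
#' @return The JSON lines, invisibly if written to `path`.
#' @export
resolved_to_json <- function(resolved, path = NULL) {
  lines <- vapply(resolved, function(el) {
    jsonlite::toJSON(list(id = el$id, layer = el$layer,
                          material = el$material, role = el$role,
                          x = el$x, y = el$y,
                          footprint = unname(el$footprint)),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  if (is.null(path)) return(unname(lines))
  writeLines(lines, path)
  invisible(unname(lines))
}

#' Export resolved geometry as a layered SVG
#'
#' Writes one `<g>` group per layer with each element's footprint as an
#' SVG polygon (y axis flipped to SVG's y-down convention at emission
#' time). Intended for visual inspection and import into vector tools.
#'
#' @param resolved a [resolve_design()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
resolved_to_svg <- function(resolved, path) {
  tab <- resolved_table(resolved)
  bb <- resolved_bbox(resolved, margin = 2)
  w <- bb[3] - bb[1]; h <- bb[4] - bb[2]
  lines <- c(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%smm" height="%smm" ',
    'viewBox="0 0 %s %s">'), fmt_num(w), fmt_num(h), fmt_num(w), fmt_num(h)))
  for (ly in sort(unique(tab$layer))) {
    lines <- c(lines, sprintf('<g id="layer%d">', ly))
    for (el in resolved[tab$id[tab$layer == ly]]) {
      fp <- el$footprint
      pts <- paste(fmt_num(fp[, 1] - bb[1]), fmt_num(bb[4] - fp[, 2]),
                   sep = ",", collapse = " ")
      lines <- c(lines, sprintf(
        '<polygon points="%s" fill="none" stroke="black" stroke-width="0.1"/>',
        pts))
    }
    lines <- c(lines, "</g>")
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

resolved_bbox <- function(resolved, margin = 0) {
  xs <- unlist(lapply(resolved, function(e) e$footprint[, 1]))
  ys <- unlist(lapply(resolved, function(e) e$footprint[, 2]))
  c(min(xs) - margin, min(ys) - margin, max(xs) + margin, max(ys) + margin)
}
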