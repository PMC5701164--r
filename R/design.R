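#' Placement of a node relative to its parent
#'
#' Every node in a device tree is positioned relative to its parent by an
#' angle, a distance and an attachment rule; nothing in a design carries an
#' absolute coordinate, which is what makes whole-device refactoring a
#' single-parameter edit.
#'
#' @param angle direction from the parent in degrees, counter-clockwise,
#'   0 along +x. Normalized to `[0, 360)`.
#' @param dist distance in mm, or an arithmetic expression string over the
#'   design's parameters (e.g. `"2*L"`). Must evaluate to a finite
#'   non-negative number.
#' @param attach `"center"`: the child's anchor sits at
#'   `parent anchor + dist * (cos angle, sin angle)`. `"abut"`: the child
#'   is pushed out along `angle` until its near boundary touches the
#'   parent's boundary (plus `dist` of clearance); rectangles attached this
#'   way lie lengthwise along `angle` with their anchor on the near edge,
#'   so a channel of length `l` abutting a circle of diameter `d` starts at
#'   the circle's rim and ends at `d/2 + l`.
#' @return An object of class `pad_placement`.
#' @export
placement <- function(angle = 0, dist = 0, attach = c("center", "abut")) {
  structure(list(angle = angle, dist = dist, attach = match.arg(attach)),
            class = "pad_placement")
}

#' Design node: a shape plus its relative placement and layer
#'
#' @param id unique token identifying the node across the design.
#' @param shape a [pad_shape][shapes] object.
#' @param placement a [placement()] object.
#' @param layer layer index the element lands on; `NA` inherits the
#'   parent's layer. A child may sit on its parent's layer, an adjacent
#'   layer, or two layers away across a declared adhesive layer (in which
#'   case a connecting hole is generated automatically on the adhesive).
#' @param children list of child `pad_node`s, resolved in declaration order.
#' @return An object of class `pad_node`.
#' @export
pad_node <- function(id, shape, placement = upadcad::placement(),
                     layer = NA_integer_, children = list()) {
  structure(list(id = as.character(id), shape = shape, placement = placement,
                 layer = as.integer(layer), children = children),
            class = "pad_node")
}

#' Layer declaration
#'
#' @param index positive integer; 1 is the top of the stack (the
#'   sample-application side), indices contiguous.
#' @param material `"paper"`, `"adhesive"` or `"membrane"`.
#' @param mode render mode: `"wax_full"` (white channels on a black
#'   background), `"wax_buffered"` (white channels surrounded by
#'   shape-fitting black borders, which use less wax), or `"cut"` (outline
#'   paths for a knife plotter or laser cutter).
#' @return An object of class `pad_layer`.
#' @export
pad_layer <- function(index, material = c("paper", "adhesive", "membrane"),
                      mode = c("wax_buffered", "wax_full", "cut")) {
  structure(list(index = as.integer(index),
                 material = match.arg(material),
                 mode = match.arg(mode)),
            class = "pad_layer")
}

#' Device design: parameters, layer stack and node forest
#'
#' The in-memory form of a design script: named numeric parameters that
#' expressions may reference, the ordered layer stack, and the forest of
#' relatively-placed nodes.
#'
#' @param name design name.
#' @param params named numeric vector/list of parameters.
#' @param layers list of [pad_layer()] declarations, indices contiguous
#'   from 1.
#' @param roots list of root [pad_node()]s; a root's placement is taken
#'   relative to the global origin.
#' @param defaults list of device-wide defaults: `border` (buffered border
#'   width, mm), `cut_stroke` (cut path stroke width, mm), `hole`
#'   (override diameter for auto-generated adhesive holes; `NULL` means
#'   min of the connected flow widths).
#' @param sheet optional [sheet_spec()] for page tiling.
#' @return An object of class `pad_design`.
#' @export
pad_design <- function(name, params = list(), layers = list(), roots = list(),
                       defaults = list(), sheet = NULL) {
  defs <- utils::modifyList(list(border = 1.5, cut_stroke = 0.2, hole = NULL),
                            defaults)
  structure(list(name = as.character(name),
                 params = as.list(params),
                 layers = layers,
                 roots = roots,
                 defaults = defs,
                 sheet = sheet),
            class = "pad_design")
}

#' @export
print.pad_design <- function(x, ...) {
  cat("<pad_design '", x$name, "'> ", length(x$layers), " layer(s), ",
      length(design_node_ids(x)), " node(s), ",
      length(x$params), " parameter(s)\n", sep = "")
  invisible(x)
}

# ---- tree traversal helpers -------------------------------------------------

walk_nodes <- function(nodes, f, depth = 1L) {
  for (nd in nodes) {
    f(nd, depth)
    walk_nodes(nd$children, f, depth + 1L)
  }
  invisible(NULL)
}

design_node_ids <- function(design) {
  ids <- character(0)
  walk_nodes(design$roots, function(nd, d) ids[[length(ids) + 1L]] <<- nd$id)
  ids
}

# apply `f(node)` to the node with the given id, rebuilding the tree
modify_node <- function(nodes, id, f, found = new.env()) {
  lapply(nodes, function(nd) {
    if (identical(nd$id, id)) {
      found$hit <- TRUE
      nd <- f(nd)
    }
    nd$children <- modify_node(nd$children, id, f, found)
    nd
  })
}

layer_lookup <- function(design) {
  idx <- vapply(design$layers, `[[`, integer(1), "index")
  stats::setNames(design$layers, as.character(idx))
}

layer_material <- function(design, index) {
  ly <- layer_lookup(design)[[as.character(index)]]
  if (is.null(ly)) NA_character_ else ly$material
}

# ---- validation -------------------------------------------------------------

#' Validate a device design
#'
#' Checks every structural invariant of the design model and returns the
#' violations as data, never as a condition: strictly positive dimensions,
#' simple polygons with at least three vertices, angles and distance
#' expressions that evaluate to finite non-negative numbers over the
#' declared parameters, a contiguous layer stack starting at 1, unique node
#' ids (a duplicated id is how an aliasing cycle manifests in a value-based
#' tree), and the layer-adjacency rule for cross-layer connections.
#'
#' `validate()` is pure; a design with an empty violation list is accepted
#' by [resolve_design()] without error.
#'
#' @param design a [pad_design()].
#' @return A data.frame with columns `where` (node id or `layer:<i>` or
#'   `design`), `rule`, and `message`; zero rows iff the design is valid.
#' @export
validate <- function(design) {
  v <- list()
  bad <- function(where, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(where = where, rule = rule,
                                       message = message)
  }

  idx <- vapply(design$layers, `[[`, integer(1), "index")
  if (length(idx) && !identical(sort(idx), seq_along(idx)))
    bad("design", "layers_contiguous",
        "layer indices must be unique and contiguous from 1")

  ids <- design_node_ids(design)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup)
    bad(d, "unique_id", sprintf("node id '%s' appears more than once", d))

  declared <- sort(idx)
  params <- design$params

  check_expr <- function(x, what, id, nonneg = FALSE) {
    val <- tryCatch(num_field(x, params), error = function(e) e)
    if (inherits(val, "error")) {
      bad(id, "expression", sprintf("%s: %s", what, conditionMessage(val)))
      return(NA_real_)
    }
    if (!is.finite(val)) {
      bad(id, "expression", sprintf("%s does not evaluate to a finite number",
                                    what))
      return(NA_real_)
    }
    if (nonneg && val < 0)
      bad(id, "expression", sprintf("%s is negative", what))
    val
  }

  check_node <- function(nd, parent_layer) {
    sh <- nd$shape
    switch(sh$kind,
      circle = {
        d <- check_expr(sh$d, "circle diameter", nd$id)
        if (isTRUE(d <= 0))
          bad(nd$id, "positive_dims", "circle diameter must be > 0")
      },
      rect = {
        l <- check_expr(sh$len, "rect length", nd$id)
        w <- check_expr(sh$w, "rect width", nd$id)
        if (isTRUE(l <= 0) || isTRUE(w <= 0))
          bad(nd$id, "positive_dims", "rect dimensions must be > 0")
      },
      polygon = {
        if (nrow(sh$vertices) < 3)
          bad(nd$id, "polygon_simple", "polygon needs at least 3 vertices")
        else if (!is_simple_ring(sh$vertices))
          bad(nd$id, "polygon_simple", "polygon is self-intersecting")
      },
      text = {
        h <- check_expr(sh$height, "text height", nd$id)
        if (isTRUE(h <= 0))
          bad(nd$id, "positive_dims", "text height must be > 0")
      })

    check_expr(nd$placement$angle, "placement angle", nd$id)
    check_expr(nd$placement$dist, "placement distance", nd$id, nonneg = TRUE)

    layer <- if (is.na(nd$layer)) parent_layer else nd$layer
    if (!is.na(layer) && !(layer %in% declared))
      bad(nd$id, "layer_declared",
          sprintf("node '%s' references undeclared layer %d", nd$id, layer))
    else if (!is.na(parent_layer) && !is.na(layer)) {
      gap <- abs(layer - parent_layer)
      if (gap > 2L)
        bad(nd$id, "layer_adjacent",
            sprintf("node '%s' jumps %d layers from its parent", nd$id, gap))
      else if (gap == 2L) {
        mid <- (layer + parent_layer) %/% 2L
        if (!identical(layer_material(design, mid), "adhesive"))
          bad(nd$id, "layer_adjacent",
              sprintf("node '%s' skips non-adhesive layer %d", nd$id, mid))
      }
    }
    for (ch in nd$children) check_node(ch, layer)
  }
  for (r in design$roots) check_node(r, NA_integer_)

  if (length(v)) do.call(rbind, v)
  else data.frame(where = character(0), rule = character(0),
                  message = character(0))
}

# simple-ring test: no two non-adjacent edges intersect
is_simple_ring <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(v[i, ], v[i %% n + 1L, ])
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_intersect(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(a, b) {
  d1 <- cross2(b[2, ] - b[1, ], a[1, ] - b[1, ])
  d2 <- cross2(b[2, ] - b[1, ], a[2, ] - b[1, ])
  d3 <- cross2(a[2, ] - a[1, ], b[1, ] - a[1, ])
  d4 <- cross2(a[2, ] - a[1, ], b[2, ] - a[1, ])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, s) {
    cross2(s[2, ] - s[1, ], p - s[1, ]) == 0 &&
      min(s[, 1]) <= p[1] && p[1] <= max(s[, 1]) &&
      min(s[, 2]) <= p[2] && p[2] <= max(s[, 2])
  }
  (d1 == 0 && on_seg(a[1, ], b)) || (d2 == 0 && on_seg(a[2, ], b)) ||
  (d3 == 0 && on_seg(b[1, ], a)) || (d4 == 0 && on_seg(b[2, ], a))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# ---- adhesive hole auto-generation -----------------------------------------

#' Insert auto-generated adhesive holes
#'
#' Multi-layer devices are assembled from patterned paper affixed with
#' double-sided adhesive film; wherever fluid must pass between two paper
#' layers, the adhesive in between needs a cut hole, and those holes must
#' stay concentric with the zones they connect. `auto_holes()` walks the
#' tree and, for every flow child placed two layers below its flow parent
#' across a declared adhesive layer, inserts a circular hole node on the
#' adhesive layer: the hole inherits the child's placement and the child is
#' re-parented concentric on the hole (distance 0), so the alignment
#' guarantee survives any later refactoring. The hole diameter is the
#' smaller of the two connected flow widths unless `defaults$hole`
#' overrides it. Auto-holes are ordinary counted elements with ids
#' `<child id>__hole`.
#'
#' The pass is idempotent; [resolve_design()] and [count_elements()] apply
#' it implicitly.
#'
#' @param design a [pad_design()].
#' @return The design with hole nodes inserted.
#' @export
auto_holes <- function(design) {
  params <- design$params
  override <- design$defaults$hole

  insert <- function(nd, layer) {
    nd$children <- lapply(nd$children, function(ch) {
      ch_layer <- if (is.na(ch$layer)) layer else ch$layer
      gap <- ch_layer - layer
      needs <- !is.na(layer) && abs(gap) == 2L &&
        identical(layer_material(design, layer + gap %/% 2L), "adhesive") &&
        identical(nd$shape$role, "flow") && identical(ch$shape$role, "flow")
      if (needs) {
        hd <- if (!is.null(override)) override else
          min(flow_width(nd$shape, params), flow_width(ch$shape, params))
        hole <- pad_node(paste0(ch$id, "__hole"),
                         circle_shape(hd),
                         ch$placement,
                         layer = layer + gap %/% 2L)
        ch$placement <- placement(angle = ch$placement$angle, dist = 0,
                                  attach = "center")
        hole$children <- list(insert(ch, ch_layer))
        hole
      } else {
        insert(ch, ch_layer)
      }
    })
    nd
  }

  design$roots <- lapply(design$roots, function(r) {
    insert(r, if (is.na(r$layer)) 1L else r$layer)
  })
  design
}
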