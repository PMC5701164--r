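#' Shape primitives
#'
#' Constructors for the geometric primitives a device is built from.
#' All dimensions are millimetres. A shape has a `role`:
#' \describe{
#'   \item{flow}{a hydrophilic zone or channel; participates in
#'     connectivity, buffering and adhesive-hole generation.}
#'   \item{cut}{a piece to be cut out (2DPN networks, adhesive films).}
#'   \item{decor}{ink that is printed but carries no fluid (text labels);
#'     never joins a flow network.}
#' }
#' Dimension arguments (`d`, `len`, `w`) may be numbers or arithmetic
#' expression strings over the design's named parameters (e.g. `"2*L"`);
#' expressions are evaluated at resolve time so parameter edits re-layout
#' the design.
#'
#' @param d circle diameter (mm or expression).
#' @param len,w rectangle length and width (mm or expressions).
#' @param rot optional rectangle/polygon orientation in degrees; a
#'   rectangle defaults to lying lengthwise along its placement angle.
#' @param vertices polygon vertices, an n x 2 matrix (or two-column
#'   data.frame) of offsets in mm about the shape's own anchor; at least
#'   3 vertices, simple (non-self-intersecting).
#' @param string,height,rotation,font text content, cap height in mm,
#'   rotation in degrees, and font family for text labels.
#' @param role one of `"flow"`, `"cut"`, `"decor"` (text is always decor).
#' @return An object of class `pad_shape`.
#' @examples
#' circle_shape(3)
#' rect_shape("L", 1.2)
#' polygon_shape(cbind(c(0, 4, 2), c(0, 0, 3)))
#' text_shape("A1", height = 3)
#' @name shapes
NULL

#' @rdname shapes
#' @export
circle_shape <- function(d, role = "flow") {
  new_shape(list(kind = "circle", d = d, role = match.arg(role, shape_roles())))
}

#' @rdname shapes
#' @export
rect_shape <- function(len, w, rot = NULL, role = "flow") {
  new_shape(list(kind = "rect", len = len, w = w, rot = rot,
                 role = match.arg(role, shape_roles())))
}

#' @rdname shapes
#' @export
polygon_shape <- function(vertices, rot = 0, role = "flow") {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  new_shape(list(kind = "polygon", vertices = v, rot = rot,
                 role = match.arg(role, shape_roles())))
}

#' @rdname shapes
#' @export
text_shape <- function(string, height, rotation = 0, font = "sans") {
  new_shape(list(kind = "text", string = as.character(string),
                 height = height, rotation = rotation, font = font,
                 role = "decor"))
}

shape_roles <- function() c("flow", "cut", "decor")

new_shape <- function(x) structure(x, class = "pad_shape")

#' @export
print.pad_shape <- function(x, ...) {
  dims <- switch(x$kind,
    circle  = paste0("d=", fmt_num(x$d)),
    rect    = paste0("len=", fmt_num(x$len), " w=", fmt_num(x$w)),
    polygon = paste0(nrow(x$vertices), " vertices"),
    text    = paste0('"', x$string, '" h=', fmt_num(x$height)))
  cat("<pad_shape ", x$kind, " ", dims, " role=", x$role, ">\n", sep = "")
  invisible(x)
}

# number of chords used to polygonalize circles; offsets of true circles are
# transcendental so all circle geometry is carried as a regular n-gon
circle_segments <- function() getOption("upadcad.circle_segments", 128L)

# unit vector at `deg` degrees, counter-clockwise from +x; cospi/sinpi keep
# axis-aligned and dist-0 placements exact in floating point
unit_vec <- function(deg) {
  a <- (deg %% 360) / 180
  c(cospi(a), sinpi(a))
}

circle_ring <- function(r, n = circle_segments()) {
  a <- 2 * (seq_len(n) - 1) / n
  cbind(r * cospi(a), r * sinpi(a))
}

rot_mat <- function(deg) {
  a <- (deg %% 360) / 180
  matrix(c(cospi(a), sinpi(a), -sinpi(a), cospi(a)), 2, 2)
}

# Local footprint polygon (n x 2 matrix, mm) about the shape's anchor.
# For attach = "abut" rectangles the anchor is the near-edge midpoint and the
# rectangle extends [0, len] along its orientation; otherwise the anchor is
# the shape's centre. `theta` is the placement angle, used as the default
# orientation of rectangles.
local_footprint <- function(shape, theta, attach, params) {
  switch(shape$kind,
    circle = circle_ring(num_field(shape$d, params) / 2),
    rect = {
      len <- num_field(shape$len, params)
      w   <- num_field(shape$w, params)
      rot <- if (is.null(shape$rot)) theta else num_field(shape$rot, params)
      xs <- if (identical(attach, "abut")) c(0, len) else c(-len / 2, len / 2)
      base <- cbind(c(xs[1], xs[2], xs[2], xs[1]),
                    c(-w / 2, -w / 2, w / 2, w / 2))
      base %*% t(rot_mat(rot))
    },
    polygon = {
      rot <- num_field(if (is.null(shape$rot)) 0 else shape$rot, params)
      if (rot == 0) shape$vertices else shape$vertices %*% t(rot_mat(rot))
    },
    text = {
      # nominal metric box; device font metrics are not consulted during
      # layout so resolution is deterministic and device-free
      h <- num_field(shape$height, params)
      wd <- 0.6 * h * nchar(shape$string)
      base <- cbind(c(-wd / 2, wd / 2, wd / 2, -wd / 2),
                    c(-h / 2, -h / 2, h / 2, h / 2))
      base %*% t(rot_mat(num_field(shape$rotation, params)))
    },
    stop("unknown shape kind: ", shape$kind))
}

# support function: extent of a local footprint along direction `deg`,
# measured from the anchor. Drives attach = "abut" placement.
support_extent <- function(footprint, deg) {
  u <- unit_vec(deg)
  max(footprint %*% u)
}

# characteristic flow width, used for auto-generated adhesive hole diameters
flow_width <- function(shape, params) {
  switch(shape$kind,
    circle  = num_field(shape$d, params),
    rect    = num_field(shape$w, params),
    polygon = min(diff(range(shape$vertices[, 1])),
                  diff(range(shape$vertices[, 2]))),
    text    = NA_real_)
}

# a shape dimension field: numeric, or an expression string over params
num_field <- function(x, params) {
  if (is.numeric(x)) return(as.numeric(x))
  eval_expression(x, params)
}

fmt_num <- function(x) {
  if (is.character(x)) return(x)
  sprintf("%.10g", x)
}
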