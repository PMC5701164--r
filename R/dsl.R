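#' Evaluate an arithmetic parameter expression
#'
#' Design scripts position and size shapes with small arithmetic
#' expressions over named parameters (e.g. a channel of length `"2*L"`),
#' which is what makes a whole device refactorable by editing a single
#' number. The expression language is deliberately tiny: numeric literals
#' (decimal point always `"."`, independent of locale), declared parameter
#' tokens, `+ - * /`, unary minus, and parentheses, with conventional
#' precedence. Nothing else evaluates: the string is charset-checked, every
#' identifier must be a declared parameter, and the parsed syntax tree is
#' walked so that only whitelisted arithmetic operators run.
#'
#' @param expr expression string (a plain number is accepted too).
#' @param params named list/vector of parameter values.
#' @return A single finite number.
#' @section Errors: undeclared token; malformed syntax; division by zero or
#'   any non-finite result.
#' @examples
#' eval_expression("2*L", list(L = 12))   # 24
#' eval_expression("3+4*2", list())       # 11
#' @export
eval_expression <- function(expr, params = list()) {
  if (is.numeric(expr)) return(as.numeric(expr))
  stopifnot(is.character(expr), length(expr) == 1L)
  if (!grepl("^[A-Za-z0-9_+*/().[:space:]-]*$", expr))
    stop("expression contains illegal characters: ", expr, call. = FALSE)
  toks <- regmatches(expr, gregexpr("[A-Za-z_][A-Za-z0-9_]*", expr))[[1]]
  unknown <- setdiff(unique(toks), names(params))
  if (length(unknown))
    stop("undeclared parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ast <- tryCatch(str2lang(expr),
                  error = function(e) stop("bad expression '", expr, "': ",
                                           conditionMessage(e), call. = FALSE))
  val <- eval_ast(ast, params, expr)
  if (!is.finite(val))
    stop("expression '", expr, "' does not evaluate to a finite number",
         " (division by zero?)", call. = FALSE)
  val
}

eval_ast <- function(node, params, expr) {
  if (is.numeric(node)) return(as.numeric(node))
  if (is.name(node)) {
    return(as.numeric(params[[as.character(node)]]))
  }
  if (is.call(node)) {
    op <- as.character(node[[1]])
    if (op == "(") return(eval_ast(node[[2]], params, expr))
    if (op %in% c("+", "-") && length(node) == 2L) {
      v <- eval_ast(node[[2]], params, expr)
      return(if (op == "-") -v else v)
    }
    if (op %in% c("+", "-", "*", "/") && length(node) == 3L) {
      a <- eval_ast(node[[2]], params, expr)
      b <- eval_ast(node[[3]], params, expr)
      return(switch(op, `+` = a + b, `-` = a - b, `*` = a * b, `/` = a / b))
    }
  }
  stop("unsupported construct in expression '", expr, "'", call. = FALSE)
}

# ---- parsing ---------------------------------------------------------------

#' Parse a device script
#'
#' Reads the plain-text `.apad` design format. The format is line-oriented,
#' UTF-8, with `#` starting a comment:
#'
#' \preformatted{
#' device fig2
#' param L = 12
#' layer 1 paper wax_buffered
#' layer 2 adhesive $CUT
#' default border=1.5 cut_stroke=0.2
#' sheet page=8.5x11in margin=6 spacing=3 dpi=600
#'
#' > circle id=center d=6 layer=1
#' >> rect id=arm1 len=L w=1.2 angle=90 attach=abut
#' >>> circle id=zone1 d=4 attach=abut
#' }
#'
#' Node lines start with one `>` per tree depth (a node at depth d+1 is a
#' child of the nearest preceding node at depth d), then the shape kind and
#' `key=value` properties. Numeric-valued properties accept arithmetic
#' expressions over the declared parameters, kept as strings and evaluated
#' at resolve time. `$CUT` on a layer line is an alias for the `cut` render
#' mode. Every node records its source line for error reporting.
#'
#' @param text the script, as a single string, a character vector of lines,
#'   or a file path (see `is_path`).
#' @param is_path if `TRUE`, `text` is a file path. Defaults to treating
#'   single-element strings without newlines that name an existing file as
#'   paths.
#' @return A validated [pad_design()]; parsing stops with an informative
#'   error (naming the line) otherwise.
#' @export
parse_script <- function(text, is_path = NULL) {
  if (is.null(is_path))
    is_path <- length(text) == 1L && !grepl("\n", text) && file.exists(text)
  lines <- if (is_path) readLines(text, warn = FALSE, encoding = "UTF-8")
           else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text

  name <- "design"
  params <- list()
  layers <- list()
  defaults <- list()
  sheet <- NULL
  roots <- list()
  stack <- list()   # stack[[d]] = path of list-indices to the depth-d node

  perr <- function(i, ...) stop("line ", i, ": ", ..., call. = FALSE)

  get_node <- function(path) {
    nd <- roots[[path[1]]]
    for (k in path[-1]) nd <- nd$children[[k]]
    nd
  }
  set_node <- function(path, nd) {
    if (length(path) == 1L) { roots[[path[1]]] <<- nd; return(invisible()) }
    parent_path <- path[-length(path)]
    parent <- get_node(parent_path)
    parent$children[[path[length(path)]]] <- nd
    set_node(parent_path, parent)
  }

  auto_id <- 0L
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next

    if (startsWith(ln, ">")) {
      depth <- nchar(sub("^(>+).*$", "\\1", ln))
      rest <- trimws(sub("^>+\\s*", "", ln))
      if (depth > length(stack) + 1L)
        perr(i, "node at depth ", depth,
             " has no parent at depth ", depth - 1L)
      toks <- tokenize_props(rest, i)
      kind <- toks$kind
      if (is.null(kind)) perr(i, "node line missing a shape kind")
      props <- toks$props
      nd <- tryCatch(node_from_props(kind, props, i),
                     error = function(e) perr(i, conditionMessage(e)))
      if (is.na(nd$id)) {
        auto_id <- auto_id + 1L
        nd$id <- paste0("n", auto_id)
      }
      attr(nd, "src") <- i
      if (depth == 1L) {
        roots[[length(roots) + 1L]] <- nd
        stack <- list(length(roots))
      } else {
        parent_path <- stack[[depth - 1L]]
        parent <- get_node(parent_path)
        parent$children[[length(parent$children) + 1L]] <- nd
        set_node(parent_path, parent)
        stack[[depth]] <- c(parent_path, length(parent$children))
        stack <- stack[seq_len(depth)]
      }
      next
    }

    word <- sub("\\s.*$", "", ln)
    rest <- trimws(sub("^\\S+\\s*", "", ln))
    switch(word,
      device = { name <- rest },
      param = {
        m <- regmatches(rest, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$",
                                      rest))[[1]]
        if (length(m) != 3L) perr(i, "malformed param line")
        val <- tryCatch(eval_expression(m[3], params),
                        error = function(e) perr(i, conditionMessage(e)))
        params[[m[2]]] <- val
      },
      layer = {
        parts <- strsplit(rest, "\\s+")[[1]]
        if (length(parts) < 2L) perr(i, "malformed layer line")
        mode <- if (length(parts) >= 3L) parts[3] else "wax_buffered"
        if (identical(toupper(mode), "$CUT")) mode <- "cut"
        ly <- tryCatch(pad_layer(as.integer(parts[1]), parts[2], mode),
                       error = function(e) perr(i, conditionMessage(e)))
        layers[[length(layers) + 1L]] <- ly
      },
      default = {
        kv <- tokenize_props(paste("x", rest), i)$props
        for (k in names(kv)) {
          defaults[[k]] <- suppressWarnings(as.numeric(kv[[k]]))
          if (is.na(defaults[[k]])) perr(i, "bad default value for ", k)
        }
      },
      sheet = {
        kv <- tokenize_props(paste("x", rest), i)$props
        sheet <- tryCatch(sheet_from_props(kv),
                          error = function(e) perr(i, conditionMessage(e)))
      },
      perr(i, "unrecognized directive '", word, "'")
    )
  }

  design <- pad_design(name, params, layers, roots, defaults, sheet)
  viol <- validate(design)
  if (nrow(viol))
    stop("script produced an invalid design:\n",
         paste(sprintf("  [%s] %s", viol$where, viol$message), collapse = "\n"),
         call. = FALSE)
  design
}

# split "kind key=value key=\"quoted value\" ..." into kind + named props
tokenize_props <- function(s, lineno) {
  toks <- regmatches(s, gregexpr('[^"[:space:]]+="[^"]*"|[^[:space:]]+', s))[[1]]
  if (!length(toks)) return(list(kind = NULL, props = list()))
  kind <- toks[1]
  props <- list()
  for (t in toks[-1]) {
    m <- regmatches(t, regexec('^([A-Za-z_][A-Za-z0-9_]*)=(.*)$', t))[[1]]
    if (length(m) != 3L)
      stop("malformed property '", t, "'", call. = FALSE)
    val <- m[3]
    if (startsWith(val, '"')) val <- substr(val, 2L, nchar(val) - 1L)
    props[[m[2]]] <- val
  }
  list(kind = kind, props = props)
}

prop_numexpr <- function(v) {
  # keep expressions as strings; collapse pure numeric literals to numbers
  n <- suppressWarnings(as.numeric(v))
  if (!is.na(n) && grepl("^[-+0-9.eE]+$", v)) n else v
}

node_from_props <- function(kind, p, lineno) {
  role <- p$role %||% switch(kind, text = "decor", "flow")
  shape <- switch(kind,
    circle = circle_shape(prop_numexpr(p$d %||% stop("circle needs d")),
                          role = role),
    rect = rect_shape(prop_numexpr(p$len %||% stop("rect needs len")),
                      prop_numexpr(p$w %||% stop("rect needs w")),
                      rot = if (!is.null(p$rot)) prop_numexpr(p$rot),
                      role = role),
    polygon = polygon_shape(parse_pts(p$pts %||% stop("polygon needs pts")),
                            rot = prop_numexpr(p$rot %||% "0"),
                            role = role),
    text = text_shape(p$text %||% stop("text needs text"),
                      prop_numexpr(p$h %||% stop("text needs h")),
                      rotation = prop_numexpr(p$rot %||% "0"),
                      font = p$font %||% "sans"),
    stop("unknown shape kind '", kind, "'"))
  pl <- placement(angle = prop_numexpr(p$angle %||% "0"),
                  dist = prop_numexpr(p$dist %||% "0"),
                  attach = p$attach %||% "center")
  pad_node(p$id %||% NA_character_, shape, pl,
           layer = if (is.null(p$layer)) NA_integer_ else as.integer(p$layer))
}

parse_pts <- function(s) {
  pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(pairs) != 2L)) stop("malformed pts '", s, "'")
  m <- t(vapply(pairs, as.numeric, numeric(2)))
  if (anyNA(m)) stop("malformed pts '", s, "'")
  m
}

sheet_from_props <- function(p) {
  pg <- p$page %||% stop("sheet needs page=WxH{in,mm}")
  m <- regmatches(pg, regexec("^([0-9.]+)x([0-9.]+)(in|mm)$", pg))[[1]]
  if (length(m) != 4L) stop("malformed page '", pg, "'")
  f <- if (m[4] == "in") 25.4 else 1
  sheet_spec(width = as.numeric(m[2]) * f, height = as.numeric(m[3]) * f,
             margin = as.numeric(p$margin %||% "5"),
             spacing = as.numeric(p$spacing %||% "2"),
             dpi = as.numeric(p$dpi %||% "600"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- serialization ---------------------------------------------------------

#' Serialize a design back to script text
#'
#' Emits the canonical script form of a design: header, parameters, layer
#' declarations, defaults, sheet block, then the node forest depth-first
#' with one `>`-prefixed line per node. Serialization is deterministic
#' (identical designs give byte-identical scripts) and round-trips:
#' `parse_script(serialize_script(d))` is structurally identical to `d`.
#' Numeric values are written with up to 10 significant digits; expression
#' strings are written verbatim.
#'
#' @param design a valid [pad_design()].
#' @return A character vector of script lines.
#' @export
serialize_script <- function(design) {
  out <- c(paste("device", design$name))
  for (p in names(design$params))
    out <- c(out, paste0("param ", p, " = ", fmt_num(design$params[[p]])))
  for (ly in design$layers)
    out <- c(out, paste("layer", ly$index, ly$material, ly$mode))
  defs <- design$defaults
  def_bits <- c(
    if (!identical(defs$border, 1.5)) paste0("border=", fmt_num(defs$border)),
    if (!identical(defs$cut_stroke, 0.2))
      paste0("cut_stroke=", fmt_num(defs$cut_stroke)),
    if (!is.null(defs$hole)) paste0("hole=", fmt_num(defs$hole)))
  if (length(def_bits)) out <- c(out, paste("default", paste(def_bits, collapse = " ")))
  if (!is.null(design$sheet)) {
    sh <- design$sheet
    out <- c(out, sprintf("sheet page=%sx%smm margin=%s spacing=%s dpi=%s",
                          fmt_num(sh$width), fmt_num(sh$height),
                          fmt_num(sh$margin), fmt_num(sh$spacing),
                          fmt_num(sh$dpi)))
  }
  out <- c(out, "")

  emit <- function(nd, depth) {
    sh <- nd$shape
    props <- c(id = nd$id)
    props <- c(props, switch(sh$kind,
      circle  = c(d = fmt_num(sh$d)),
      rect    = c(len = fmt_num(sh$len), w = fmt_num(sh$w),
                  if (!is.null(sh$rot)) c(rot = fmt_num(sh$rot))),
      polygon = c(pts = paste(apply(sh$vertices, 1, function(r)
                    paste(fmt_num(r[1]), fmt_num(r[2]), sep = ":")),
                    collapse = ";"),
                  if (!identical(sh$rot, 0)) c(rot = fmt_num(sh$rot))),
      text    = c(text = paste0('"', sh$string, '"'), h = fmt_num(sh$height),
                  if (!identical(sh$rotation, 0)) c(rot = fmt_num(sh$rotation)),
                  if (!identical(sh$font, "sans")) c(font = sh$font))))
    if (!identical(sh$kind, "text") && !identical(sh$role,
        switch(sh$kind, text = "decor", "flow")))
      props <- c(props, role = sh$role)
    pl <- nd$placement
    if (!identical(pl$angle, 0)) props <- c(props, angle = fmt_num(pl$angle))
    if (!identical(pl$dist, 0))  props <- c(props, dist = fmt_num(pl$dist))
    if (!identical(pl$attach, "center")) props <- c(props, attach = pl$attach)
    if (!is.na(nd$layer)) props <- c(props, layer = as.character(nd$layer))
    # expression strings may contain whitespace; quote them so they stay
    # one token
    needs_q <- grepl("[[:space:]]", props) & !startsWith(props, '"')
    props[needs_q] <- paste0('"', props[needs_q], '"')
    line <- paste0(strrep(">", depth), " ", sh$kind, " ",
                   paste(names(props), unname(props), sep = "=", collapse = " "))
    out <<- c(out, line)
    for (ch in nd$children) emit(ch, depth + 1L)
  }
  for (r in design$roots) emit(r, 1L)
  out
}

#' Write a design script to a file
#'
#' @param design a [pad_design()].
#' @param path output file path (conventionally `.apad`).
#' @return `path`, invisibly.
#' @export
write_script <- function(design, path) {
  writeLines(serialize_script(design), path, useBytes = TRUE)
  invisible(path)
}
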