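# Shared helpers: small hand-built designs and independent oracles used
# across the suite.

one_circle_design <- function() {
  pad_design("mini",
             layers = list(pad_layer(1, "paper", "wax_buffered")),
             roots = list(pad_node("a", circle_shape(5), layer = 1)))
}

# random small design generator for property-style tests: a forest of
# circles/rects with random relative placements on paper layers. Each node
# after the first attaches to a uniformly chosen earlier node (or starts a
# new root). Values are rounded so DSL round-trips are numerically exact.
random_design <- function(n_nodes = 8, n_layers = 2, p_child = 0.8) {
  layers <- lapply(seq_len(n_layers), function(i)
    pad_layer(i, "paper", sample(c("wax_buffered", "wax_full"), 1)))
  shape_i <- function() {
    if (runif(1) < 0.5) circle_shape(round(runif(1, 2, 6), 3))
    else rect_shape(round(runif(1, 4, 10), 3), round(runif(1, 1, 2), 3))
  }
  parent_of <- integer(n_nodes)
  layer_of <- integer(n_nodes)
  parent_of[1] <- 0L; layer_of[1] <- 1L
  for (i in seq_len(n_nodes)[-1]) {
    if (runif(1) < p_child) {
      p <- sample.int(i - 1L, 1)
      parent_of[i] <- p
      layer_of[i] <- max(1L, min(n_layers, layer_of[p] +
        sample(c(-1L, 0L, 1L), 1, prob = c(.15, .7, .15))))
    } else {
      parent_of[i] <- 0L
      layer_of[i] <- 1L
    }
  }
  build <- function(i) {
    kids <- lapply(which(parent_of == i), build)
    pad_node(paste0("n", i), shape_i(),
             placement(angle = round(runif(1, 0, 359), 2),
                       dist = round(runif(1, 0, 12), 3),
                       attach = sample(c("center", "abut"), 1)),
             layer = layer_of[i], children = kids)
  }
  pad_design("random", layers = layers,
             roots = lapply(which(parent_of == 0L), build))
}

# independent subtree-id oracle: ids of a node and all its descendants,
# found by a plain recursive search that shares nothing with the layout
# engine
subtree_ids <- function(design, id) {
  hit <- NULL
  find <- function(nd) {
    if (identical(nd$id, id)) hit <<- nd
    for (ch in nd$children) find(ch)
  }
  for (r in design$roots) find(r)
  if (is.null(hit)) return(character(0))
  out <- character(0)
  collect <- function(nd) {
    out <<- c(out, nd$id)
    for (ch in nd$children) collect(ch)
  }
  collect(hit)
  out
}

# brute-force pairwise polygon contact oracle (independent of polyclip):
# point-in-polygon containment plus closest approach of boundary segments
polys_touch_oracle <- function(a, b, tol = 1e-6) {
  pip <- function(p, v) {
    n <- nrow(v); j <- n; inside <- FALSE
    for (i in seq_len(n)) {
      if ((v[i, 2] > p[2]) != (v[j, 2] > p[2]) &&
          p[1] < (v[j, 1] - v[i, 1]) * (p[2] - v[i, 2]) /
                 (v[j, 2] - v[i, 2]) + v[i, 1]) inside <- !inside
      j <- i
    }
    inside
  }
  if (pip(a[1, ], b) || pip(b[1, ], a)) return(TRUE)
  seg_dist <- function(p, q, r, s) {
    d <- function(pt, u, v) {
      w <- v - u; t <- sum((pt - u) * w) / max(sum(w^2), 1e-300)
      t <- min(1, max(0, t)); sqrt(sum((u + t * w - pt)^2))
    }
    min(d(p, r, s), d(q, r, s), d(r, p, q), d(s, p, q))
  }
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p <- a[i, ]; q <- a[i %% na + 1L, ]
    for (j in seq_len(nb)) {
      r <- b[j, ]; s <- b[j %% nb + 1L, ]
      if (seg_dist(p, q, r, s) <= tol) return(TRUE)
    }
  }
  FALSE
}

expect_design_equal <- function(a, b) {
  expect_equal(strip_src(a), strip_src(b))
}

strip_src <- function(x) {
  if (is.list(x)) {
    attr(x, "src") <- NULL
    for (i in seq_along(x)) {
      v <- x[[i]]
      if (is.list(v)) x[i] <- list(strip_src(v))   # preserves NULL slots
    }
  }
  x
}
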