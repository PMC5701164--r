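test_that("roots resolve at the origin and children at closed-form offsets", {
  d <- one_circle_design()
  r <- resolve_design(d)
  expect_identical(c(r[["a"]]$x, r[["a"]]$y), c(0, 0))

  add_child <- function(angle, dist) {
    d <- one_circle_design()
    d$roots[[1]]$children <- list(
      pad_node("b", circle_shape(2), placement(angle = angle, dist = dist)))
    resolve_design(d)[["b"]]
  }
  b <- add_child(0, 10)
  expect_identical(c(b$x, b$y), c(10, 0))
  # closed-form cos/sin oracle at 240 degrees
  b240 <- add_child(240, 10)
  expect_equal(c(b240$x, b240$y), c(10 * cos(240 * pi / 180),
                                    10 * sin(240 * pi / 180)))
  expect_equal(c(b240$x, b240$y), c(-5.0, -8.66025), tolerance = 1e-5)
})

test_that("abutting channels start at the parent rim and end at d/2 + len", {
  d <- one_circle_design()   # circle d = 5
  d$roots[[1]]$children <- list(
    pad_node("ch", rect_shape(8, 1), placement(angle = 0, attach = "abut"),
             children = list(
      pad_node("z", circle_shape(3), placement(angle = 0, attach = "abut")))))
  r <- resolve_design(d)
  # channel anchor sits at the circle rim (support of the 128-gon)
  rim <- max(r[["a"]]$footprint[, 1])
  expect_equal(r[["ch"]]$x, rim)
  expect_equal(rim, 2.5, tolerance = 1e-3)
  # far end at rim + len; abutting zone centre one radius beyond
  expect_equal(max(r[["ch"]]$footprint[, 1]), rim + 8)
  expect_equal(r[["z"]]$x, rim + 8 + max(upadcad:::circle_ring(1.5)[, 1]))
})

test_that("a cross-layer child at distance 0 is centred exactly on its parent", {
  d <- make_figure2_device(12)
  r <- resolve_design(d)
  expect_identical(r[["split1"]]$x, r[["zone1"]]$x)
  expect_identical(r[["split1"]]$y, r[["zone1"]]$y)
  expect_identical(nrow(check_alignment(r, tolerance = 0)), 0L)
})

test_that("check_alignment reports a deliberately offset cross-layer pair", {
  d <- pad_design("off",
    layers = list(pad_layer(1, "paper"), pad_layer(2, "paper")),
    roots = list(pad_node("a", circle_shape(4), layer = 1,
                 children = list(pad_node("b", circle_shape(4),
                   placement(angle = 0, dist = 1), layer = 2)))))
  bad <- check_alignment(resolve_design(d), tolerance = 0.5)
  expect_identical(bad$child, "b")
  expect_equal(bad$offset, 1)
  expect_identical(nrow(check_alignment(resolve_design(d), tolerance = 2)), 0L)
})

test_that("resolution is translation-equivariant in the root placement", {
  # wrapping every root under a parent displaced by v translates every
  # element centre by exactly v
  set.seed(8)
  for (k in 1:5) {
    d <- random_design(n_nodes = 12)
    for (i in seq_along(d$roots)) d$roots[[i]]$placement$attach <- "center"
    r0 <- resolve_design(d)
    shift <- c(17, -6)
    d2 <- d
    d2$roots <- lapply(seq_along(d$roots), function(i) {
      pad_node(paste0("shim", i), circle_shape(0.5),
               placement(angle = 0, dist = 17), layer = 1,
               children = list(local({
                 rt <- d$roots[[i]]
                 rt$placement <- placement(angle = rt$placement$angle,
                                           dist = rt$placement$dist)
                 rt
               })))
    })
    # shims sit at (17, 0); now push them down by 6 via a second wrap
    d2$roots <- lapply(d2$roots, function(s) {
      s$placement <- placement(angle = 270, dist = 6)
      w <- pad_node(paste0("w", s$id), circle_shape(0.5),
                    placement(angle = 0, dist = 17), layer = 1,
                    children = list(s))
      w
    })
    r2 <- resolve_design(d2)
    for (id in names(r0)) {
      expect_equal(r2[[id]]$x, r0[[id]]$x + shift[1])
      expect_equal(r2[[id]]$y, r0[[id]]$y + shift[2])
    }
  }
})

test_that("an empty edit set leaves the resolution identical", {
  d <- make_case_study("splitter3D", list(samples = 1))
  expect_identical(resolve_design(refactor_design(d)), resolve_design(d))
})

test_that("refactor errors on unknown parameters, nodes and properties", {
  d <- make_figure2_device()
  expect_error(refactor_design(d, params = list(Q = 1)), "unknown parameter")
  expect_error(refactor_design(d, nodes = list(nope = list(len = 2))),
               "no node")
  expect_error(refactor_design(d, nodes = list(arm1 = list(frob = 2))),
               "unknown property")
})

test_that("single-node placement edits move exactly the node and its subtree (property)", {
  set.seed(101)
  n_cases <- 60
  for (k in seq_len(n_cases)) {
    d <- random_design(n_nodes = sample(4:14, 1))
    ids <- sample(names(resolve_design(d)), 1)
    r0 <- resolve_design(d)
    d2 <- refactor_design(d, nodes = stats::setNames(
      list(list(dist = round(runif(1, 13, 20), 3))), ids))
    df <- diff_positions(r0, resolve_design(d2))
    # brute-force oracle: the edited node plus all its descendants
    expected <- subtree_ids(d, ids)
    expect_setequal(df$moved, expected)
  }
})

test_that("diff_positions is empty on identical resolutions and errors on id mismatch", {
  d <- make_figure2_device()
  r <- resolve_design(d)
  expect_identical(diff_positions(r, r)$n_moved, 0L)
  r2 <- r[-1]
  class(r2) <- "pad_resolved"
  expect_error(diff_positions(r, r2), "id set")
})

test_that("splitter per-layer counts follow the closed-form stage formula", {
  # with s samples and stages (2, 2, 4):
  # (s, s, 5s, 2s, 10s, 4s, 36s, 16s, 16s)
  for (s in c(1, 2, 4)) {
    d <- make_case_study("splitter3D", list(samples = s))
    ce <- count_elements(d)
    expect_identical(unname(ce$per_layer),
                     as.integer(s * c(1, 1, 5, 2, 10, 4, 36, 16, 16)))
    expect_identical(ce$total, as.integer(91 * s))
  }
})

test_that("count_elements of an empty design is zero", {
  d <- pad_design("empty", layers = list(pad_layer(1, "paper")))
  expect_identical(count_elements(d)$total, 0L)
})

test_that("lengthening one first-stage splitter channel moves 43 elements, 32 paper + 11 adhesive", {
  d <- make_case_study("splitter3D")
  r0 <- resolve_design(d)
  d1 <- refactor_design(d, nodes = list(s2_c2 = list(len = "len1*2")))
  df <- diff_positions(r0, resolve_design(d1), tolerance = 1e-6)
  expect_false("s2_c2" %in% df$moved)  # the edited channel's anchor is fixed
  expect_identical(df$n_moved, 43L)
  expect_identical(unname(df$by_material[c("paper", "adhesive")]), c(32L, 11L))
  # and the moved set is exactly the channel's proper descendants
  expect_setequal(df$moved, setdiff(subtree_ids(auto_holes(d), "s2_c2"),
                                    "s2_c2"))
})

test_that("lengthening all 8 first-stage channels moves 344 elements", {
  d <- make_case_study("splitter3D")
  r0 <- resolve_design(d)
  d8 <- refactor_design(d, params = list(len1 = 13))
  df <- diff_positions(r0, resolve_design(d8), tolerance = 1e-6)
  expect_identical(df$n_moved, 344L)
})

test_that("resolved geometry exports to JSON lines and layered SVG", {
  d <- make_case_study("splitter1L")
  r <- resolve_design(d)
  lines <- resolved_to_json(r)
  expect_length(lines, 7)
  rec <- jsonlite::fromJSON(lines[[1]])
  expect_identical(rec$id, "center")
  expect_identical(rec$layer, 1L)

  svg <- tempfile(fileext = ".svg")
  resolved_to_svg(r, svg)
  txt <- readLines(svg)
  expect_true(any(grepl("<g id=\"layer1\">", txt)))
  expect_identical(sum(grepl("<polygon", txt)), 7L)
})
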