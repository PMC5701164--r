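test_that("disjoint circles form separate groups; an abutting chain forms one", {
  d <- pad_design("g", layers = list(pad_layer(1, "paper")),
    roots = list(pad_node("a", circle_shape(4), layer = 1),
                 pad_node("b", circle_shape(4),
                          placement(angle = 0, dist = 20), layer = 1)))
  g <- flow_components(resolve_design(d), 1)
  expect_length(g, 2)

  chain <- pad_design("c", layers = list(pad_layer(1, "paper")),
    roots = list(pad_node("a", circle_shape(4), layer = 1, children = list(
      pad_node("ch", rect_shape(6, 1), placement(angle = 0, attach = "abut"),
               children = list(
        pad_node("z", circle_shape(3),
                 placement(angle = 0, attach = "abut"))))))))
  g2 <- flow_components(resolve_design(chain), 1)
  expect_length(g2, 1)
  expect_setequal(g2[[1]]$ids, c("a", "ch", "z"))
})

test_that("the single-layer splitter is one 7-member network (brute-force oracle)", {
  r <- resolve_design(make_case_study("splitter1L"))
  g <- flow_components(r, 1)
  expect_length(g, 1)
  expect_length(g[[1]]$ids, 7)

  # independent pairwise-contact oracle + transitive closure
  els <- unname(r[order(names(r))])
  n <- length(els)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    adj[i, j] <- adj[j, i] <-
      polys_touch_oracle(els[[i]]$footprint, els[[j]]$footprint)
  reach <- adj | diag(n)
  for (k in seq_len(n)) reach <- reach | (reach %*% (reach + 0) > 0)
  expect_true(all(reach))   # everything transitively connected
})

test_that("fitted border of a circle matches the closed-form annulus area", {
  circ <- upadcad:::circle_ring(2.5)          # circle d = 5 mm
  ring <- fitted_border(circ, border = 1)
  a_expected <- pi * (3.5^2 - 2.5^2)          # 18.8496 mm^2
  expect_equal(region_area(ring), a_expected, tolerance = 0.005)
})

test_that("overlapping circles yield one connected ring smaller than two annuli", {
  c1 <- upadcad:::circle_ring(2.5)
  c2 <- sweep(upadcad:::circle_ring(2.5), 2, c(3, 0), "+")
  un <- upadcad:::region_union(list(list(upadcad:::fp_to_ring(c1)),
                                    list(upadcad:::fp_to_ring(c2))))
  ring <- fitted_border(un, border = 1)
  # connected: exactly one outer ring (positive area) and one hole
  signs <- vapply(ring, ring_area, numeric(1))
  expect_identical(sum(signs > 0), 1L)
  expect_lt(region_area(ring), 2 * pi * (3.5^2 - 2.5^2))
})

test_that("the fitted border never overlaps the flow union", {
  for (id in c("splitter1L", "splitter3D")) {
    r <- resolve_design(make_case_study(id))
    for (g in flow_components(r, if (id == "splitter1L") 1 else 3)) {
      ring <- fitted_border(g, border = 1.5)
      inter <- upadcad:::pc_op(ring, g$footprint, "intersection")
      expect_lt(abs(region_area(inter)), 1e-6)
    }
  }
})

test_that("full_field is canvas minus the flow union, and errors outside it", {
  d <- one_circle_design()
  r <- resolve_design(d)
  canvas <- c(-10, -10, 10, 10)
  region <- full_field(r, canvas)
  expect_equal(region_area(region), 400 - pi * 2.5^2, tolerance = 0.005)
  # empty layer: whole canvas inked
  empty <- structure(list(), class = "pad_resolved")
  expect_equal(region_area(full_field(empty, canvas)), 400)
  expect_error(full_field(r, c(0, 0, 1, 1)), "outside the canvas")
})

test_that("cut outline of a circle has one ring of length ~ pi * d", {
  cp <- cut_outline(upadcad:::circle_ring(5), stroke = 0.2)
  expect_length(cp$rings, 1)
  expect_equal(region_perimeter(cp$rings), pi * 10, tolerance = 0.005)
})

test_that("an annular union cuts as two opposite-orientation rings", {
  outer <- upadcad:::fp_to_ring(upadcad:::circle_ring(5))
  inner <- upadcad:::fp_to_ring(upadcad:::circle_ring(2))
  annulus <- upadcad:::pc_op(list(outer), list(inner), "minus")
  cp <- cut_outline(annulus)
  expect_length(cp$rings, 2)
  signs <- sort(sign(vapply(cp$rings, ring_area, numeric(1))))
  expect_identical(signs, c(-1, 1))
})

test_that("each 2DPN piece yields one plotter ring", {
  r <- resolve_design(make_case_study("twoDPN"))
  groups <- flow_components(r, 1, role = "cut")
  expect_length(groups, 2)   # network piece + absorbent pad
  outers <- vapply(groups, function(g)
    sum(vapply(cut_outline(g)$rings, ring_area, numeric(1)) > 0), integer(1))
  expect_identical(outers, c(1L, 1L))
})

test_that("buffered wax never exceeds full-field wax while flow area is identical", {
  for (id in c("splitter1L", "microzone96")) {
    r <- resolve_design(make_case_study(id))
    canvas <- design_canvas(r)
    wf <- wax_region(r, 1, "wax_full", canvas)
    wb <- wax_region(r, 1, "wax_buffered", canvas)
    expect_lte(region_area(wb), region_area(wf))
    # no wax inside the flow union in either mode
    for (g in flow_components(r, 1)) {
      expect_lt(abs(region_area(upadcad:::pc_op(wf, g$footprint,
                                                "intersection"))), 1e-6)
      expect_lt(abs(region_area(upadcad:::pc_op(wb, g$footprint,
                                                "intersection"))), 1e-6)
    }
  }
})

test_that("cut_outline of a re-unioned union is unchanged (idempotence)", {
  r <- resolve_design(make_case_study("splitter1L"))
  g <- flow_components(r, 1)[[1]]
  once <- cut_outline(g$footprint)
  again <- cut_outline(upadcad:::region_union(list(g$footprint)))
  expect_equal(region_perimeter(again$rings), region_perimeter(once$rings),
               tolerance = 1e-9)
  expect_equal(region_area(again$rings), region_area(once$rings),
               tolerance = 1e-9)
})
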