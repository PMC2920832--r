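test_that("cell_outline validates polygons", {
  expect_error(cell_outline(c(0, 1, 1, 0), c(0, 0, 1, 1)), "8")
  t <- seq(0, 2 * pi, length.out = 21)[-21]
  o <- cell_outline(cos(t), sin(t))
  expect_identical(o$n, 20L)
  # closing vertex dropped
  o2 <- cell_outline(c(cos(t), 1), c(sin(t), 0))
  expect_identical(o2$n, 20L)
  # octagram (star polygon {8/3}) rejected
  th <- (0:7) * 3 * (2 * pi / 8)
  expect_error(cell_outline(cos(th), sin(th)), "self-intersecting")
})

test_that("tangent and outward normal match analytic geometry", {
  # circle: tangent perpendicular to the radius
  oc <- make_outline("ellipse", semi_axes = c(5, 5), n_nodes = 100)
  for (i in c(1, 10, 37, 80)) {
    tn <- tangent_at_node(oc, i)
    radial <- deg(atan2(oc$y[i], oc$x[i]))
    d <- abs(((tn$tangent - radial - 90 + 180) %% 360) - 180)
    expect_lt(min(d, abs(180 - d)), 1)
    # normal points outward along the radius
    expect_lt(abs(((tn$normal - radial + 180) %% 360) - 180), 1)
  }
  # rectangle: mid-edge tangent parallel to the edge
  rx <- c(seq(0, 10, length.out = 5), rep(10, 3), seq(10, 0, length.out = 5),
          rep(0, 3))
  ry <- c(rep(0, 5), c(1, 2, 3), rep(4, 5), c(3, 2, 1))
  ro <- cell_outline(rx, ry)
  tn <- tangent_at_node(ro, 3)          # middle of the bottom edge
  expect_true(abs(tn$tangent) %in% c(0, 180))
  expect_equal(tn$normal, -90)
  # ellipse: outward normal within 1 degree of the analytic normal field
  t <- seq(0, 2 * pi, length.out = 151)[-151]
  a <- 7; b <- 4.5
  oe <- cell_outline(a * cos(t), b * sin(t))
  worst <- 0
  for (i in seq(1, 150, by = 7)) {
    nrm <- tangent_at_node(oe, i)$normal
    analytic <- deg(atan2(sin(t[i]) / b, cos(t[i]) / a))
    worst <- max(worst, abs(((nrm - analytic + 180) %% 360) - 180))
  }
  expect_lt(worst, 1)
  expect_error(tangent_at_node(oe, 200), "out of range")
})

test_that("tangent direction is continuous along a smooth outline", {
  o <- make_outline("ellipse", n_nodes = 150)
  tg <- sapply(seq_len(o$n), function(i) tangent_at_node(o, i)$tangent)
  d <- abs(((diff(c(tg, tg[1])) + 180) %% 360) - 180)
  expect_lt(max(d), 15)
})

test_that("inscribed and circumscribed ellipses bracket the outline", {
  # elliptical cell: both ellipses recover it
  o <- make_outline("ellipse", semi_axes = c(6, 3))
  eo <- inner_outer_ellipses(o)
  a_poly <- abs(pracma::polyarea(o$x, o$y))
  expect_equal(pi * eo$inner$semi_major * eo$inner$semi_minor, a_poly,
               tolerance = 0.02)
  expect_equal(pi * eo$outer$semi_major * eo$outer$semi_minor, a_poly,
               tolerance = 0.02)
  # unit circle
  oc <- make_outline("ellipse", semi_axes = c(1, 1))
  ec <- inner_outer_ellipses(oc)
  expect_equal(ec$inner$semi_major, 1, tolerance = 0.01)
  expect_equal(ec$outer$semi_minor, 1, tolerance = 0.01)
  # star: strict area ordering inner < polygon < outer
  os <- make_outline("star", spike_count = 5, spike_amplitude = 0.35)
  es <- inner_outer_ellipses(os)
  a_star <- abs(pracma::polyarea(os$x, os$y))
  expect_lt(pi * es$inner$semi_major * es$inner$semi_minor, a_star)
  expect_gt(pi * es$outer$semi_major * es$outer$semi_minor, a_star)
  # containment verified pointwise
  ip <- pseudowalk:::ellipse_polygon(es$inner, 512)
  expect_true(all(pracma::inpolygon(ip$x, ip$y, os$x, os$y, boundary = TRUE)))
  expect_true(all(pseudowalk:::ellipse_metric(es$outer, os$x, os$y) <= 1 + 1e-9))
})

test_that("ellipse interpolation is linear with endpoint identity", {
  inner <- ellipse_params(c(0, 0), 1, 1)
  outer <- ellipse_params(c(0, 0), 3, 3)
  expect_equal(interpolated_ellipse(inner, outer, 0), inner)
  expect_equal(interpolated_ellipse(inner, outer, 1), outer)
  mid <- interpolated_ellipse(inner, outer, 0.5)
  expect_equal(mid$semi_major, 2)
  expect_equal(mid$semi_minor, 2)
  # orientation takes the shortest path modulo 180
  e1 <- ellipse_params(c(0, 0), 2, 1, orientation = 170)
  e2 <- ellipse_params(c(0, 0), 2, 1, orientation = -170)
  expect_equal(interpolated_ellipse(e1, e2, 0.5)$orientation, 180)
})

test_that("overlap areas agree with a brute-force grid oracle", {
  # ellipse containing the cell: O = 0, I = area difference
  o <- make_outline("ellipse", semi_axes = c(4, 2), n_nodes = 120)
  big <- ellipse_params(c(0, 0), 8, 8)
  oa <- overlap_areas(o, big)
  expect_equal(oa$O, 0, tolerance = 1e-6)
  expect_equal(oa$I, pi * 64 - oa$T, tolerance = 0.01 * oa$T)
  # coincident shapes: both mismatch areas vanish
  same <- ellipse_params(c(0, 0), 4, 2)
  oas <- overlap_areas(o, same)
  expect_lt(oas$O / oas$T, 0.005)
  expect_lt(oas$I / oas$T, 0.005)
  # unit square vs the unit-area disk: O = I by construction
  sq <- cell_outline(c(0, .25, .5, .75, 1, 1, 1, 1, 1, .75, .5, .25, 0, 0, 0, 0),
                     c(0, 0, 0, 0, 0, .25, .5, .75, 1, 1, 1, 1, 1, .75, .5, .25))
  disk <- ellipse_params(c(0.5, 0.5), sqrt(1 / pi), sqrt(1 / pi))
  od <- overlap_areas(sq, disk)
  expect_equal(od$O, od$I, tolerance = 0.02)
  oracle <- grid_overlap_oracle(sq, disk)
  expect_equal(od$O, oracle$O, tolerance = 0.03)
  expect_equal(od$I, oracle$I, tolerance = 0.03)
  # star against its own base ellipse, vs the grid oracle
  os <- make_outline("star", spike_amplitude = 0.3)
  es <- inner_outer_ellipses(os)
  emid <- interpolated_ellipse(es$inner, es$outer, 0.5)
  oa2 <- overlap_areas(os, emid)
  or2 <- grid_overlap_oracle(os, emid)
  expect_equal(oa2$O, or2$O, tolerance = 0.03)
  expect_equal(oa2$I, or2$I, tolerance = 0.03)
  expect_equal(oa2$T, or2$T, tolerance = 0.03)
})

test_that("shape statistic balances O and I and is small for smooth ellipses", {
  s <- shape_psi(make_outline("ellipse"))
  expect_lt(s$psi, 0.02)
  expect_lt(abs(s$O - s$I), 1e-3 * s$T + 1e-9)
  expect_equal(s$psi, (s$O + s$I) / s$T, tolerance = 1e-9)
  expect_true(s$balanced)
  # O = I forces the intermediate ellipse area to match the cell area
  st <- shape_psi(make_outline("star", spike_amplitude = 0.3))
  e <- st$intermediate
  expect_equal(pi * e$semi_major * e$semi_minor, st$T, tolerance = 0.01)
})

test_that("shape statistic grows with spike amplitude and stays in [0, 2)", {
  amps <- c(0.05, 0.12, 0.2, 0.3, 0.4)
  psis <- sapply(amps, function(A) {
    shape_psi(make_outline("star", spike_amplitude = A))$psi
  })
  expect_true(all(diff(psis) > 0))
  expect_true(all(psis >= 0 & psis < 2))
  # realistic amoeboid range stays below the observed maximum of 0.92
  expect_true(all(psis < 0.92))
})

test_that("shape statistic is invariant under similarity transforms", {
  o <- make_outline("star", spike_amplitude = 0.25, spike_count = 6)
  base <- shape_psi(o)$psi
  th <- 0.7
  tx <- 3 * (o$x * cos(th) - o$y * sin(th)) + 11
  ty <- 3 * (o$x * sin(th) + o$y * cos(th)) - 4
  moved <- shape_psi(cell_outline(tx, ty))$psi
  expect_equal(moved, base, tolerance = 1e-3)
})
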