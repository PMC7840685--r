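test_that("H-tree branch lengths follow the level scaling law", {
  h <- generate_htree(1.4, levels = 3, L1 = 100)
  b <- assign_levels(h)$branches
  expect_equal(sort(unique(b$level)), 1:3)
  expect_equal(b$length[b$level == 2][1], 100 / 2^(1 / 1.4), tolerance = 1e-9)
  expect_equal(b$length[b$level == 3][1], 100 / 2^(2 / 1.4), tolerance = 1e-9)

  h12 <- generate_htree(1.4, levels = 12, total_length = 1000)
  b12 <- assign_levels(h12)$branches
  expect_equal(nrow(b12), 2^12 - 1) # binary doubling
  expect_equal(sum(b12$length), 1000, tolerance = 1e-6)
  expect_equal(as.vector(table(b12$level)), 2^(0:11))

  # total length constant across D values
  for (D in c(1.1, 1.7, 2.3)) {
    hD <- generate_htree(D, levels = 12, total_length = 1000)
    expect_equal(sum(assign_levels(hD)$branches$length), 1000, tolerance = 1e-6)
  }
  expect_error(generate_htree(-1, levels = 3, L1 = 10), "D_target")
  expect_error(generate_htree(1.4, levels = 0, L1 = 10), "levels")
})

test_that("fork angles are 90 degrees and 3D trees cycle branching planes", {
  h <- generate_htree(1.4, levels = 5, L1 = 50)
  ang <- measure_angles(h)
  expect_true(all(abs(ang$fork$angle - 90) < 1e-6))
  # planar version stays planar, 3D version does not
  h2 <- generate_htree(1.4, levels = 5, L1 = 50, dimensionality = "2D")
  expect_equal(diff(range(h2$nodes$z)), 0)
  expect_gt(diff(range(h$nodes$z)), 1)
})

test_that("weaving H-trees preserve topology and arc length, reproducibly", {
  w1 <- generate_weaving_htree(1.4, levels = 5, total_length = 500,
                               weave_sigma = 15, seed = 7)
  w2 <- generate_weaving_htree(1.4, levels = 5, total_length = 500,
                               weave_sigma = 15, seed = 7)
  expect_identical(w1, w2) # same seed, same arbor
  b <- assign_levels(w1)$branches
  expect_equal(nrow(b), 2^5 - 1)
  expect_equal(sum(b$length), 500, tolerance = 1e-6) # bends, does not stretch

  w3 <- generate_weaving_htree(1.4, levels = 5, total_length = 500,
                               weave_sigma = 15, seed = 8)
  expect_false(identical(w1$nodes, w3$nodes))

  # zero-noise limit is exactly the straight generator
  w0 <- generate_weaving_htree(1.4, levels = 5, total_length = 500,
                               weave_sigma = 0, seed = 7)
  expect_identical(w0, generate_htree(1.4, levels = 5, total_length = 500))

  expect_error(generate_weaving_htree(1.4, levels = 3, weave_sigma = 10,
                                      hurst = 1.2), "hurst")
})

test_that("equal-length trees have one common length and the stated fork angle", {
  e <- generate_equal_length_htree(37, levels = 3, total_length = 300)
  b <- assign_levels(e)$branches
  expect_equal(nrow(b), 7)
  expect_equal(b$length, rep(300 / 7, 7), tolerance = 1e-9)
  ang <- measure_angles(e)
  expect_true(all(abs(ang$fork$angle - 37) < 1e-6))
  expect_error(generate_equal_length_htree(200, levels = 3), "phi")

  # equalizing an existing tree preserves the total
  h <- generate_htree(1.4, levels = 3, L1 = 100)
  tot <- sum(assign_levels(h)$branches$length)
  eq <- equalize_htree(h)
  be <- assign_levels(eq)$branches
  expect_equal(sum(be$length), tot, tolerance = 1e-9)
  expect_equal(diff(range(be$length)), 0, tolerance = 1e-9)
})

test_that("toy arbors reproduce the anchored medians and degenerate cleanly", {
  t1 <- generate_toy_arbor(n_levels = 9, seed = 3)
  ang <- measure_angles(t1)
  expect_gt(nrow(ang$weave), 1e3)
  expect_lt(abs(median(ang$weave$angle) - 12), 1.2) # within 10% of 12 deg
  expect_lt(abs(median(ang$fork$angle) - 37), 3.7)  # within 10% of 37 deg
  segs <- fractalarbor:::arbor_segments(t1)
  seglen <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2 +
                 (segs$z1 - segs$z0)^2)
  expect_lt(abs(median(seglen) - 2.4), 0.24)
  expect_lt(abs(median(2 * segs$radius) - 1.4), 0.14)

  expect_identical(generate_toy_arbor(n_levels = 4, seed = 5),
                   generate_toy_arbor(n_levels = 4, seed = 5))

  # a single level gives unbranched primary paths
  t0 <- generate_toy_arbor(n_levels = 1, n_primary = 2, seed = 1)
  expect_true(all(vapply(arbor_branches(t0), `[[`, integer(1), "level") == 1L))
})

test_that("icospheres converge to the analytic sphere", {
  sp <- generate_sphere_mesh(10, 4)
  expect_equal(fractalarbor:::mesh_area(sp), 400 * pi, tolerance = 0.01)
  hm <- hull_metrics(sp)
  expect_equal(hm$A_b, 400 * pi, tolerance = 0.01)
  expect_equal(hm$V_b, 4000 * pi / 3, tolerance = 0.01)
  # the hull of a convex polyhedron's vertices is the polyhedron itself
  expect_equal(hm$A_b, fractalarbor:::mesh_area(sp), tolerance = 1e-9)
  expect_error(generate_sphere_mesh(-1), "radius")
})

test_that("fractional Gaussian noise has the stated variance and persistence", {
  set.seed(11)
  x <- rfgn(3000, hurst = 0.75)
  expect_equal(sd(x), 1, tolerance = 0.1)
  # lag-1 autocorrelation of fGn: (2^(2H) - 2)/2 = 0.41 at H = 0.75
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, (2^1.5 - 2) / 2, tolerance = 0.1)
  # H = 0.5 is white noise
  set.seed(12)
  y <- rfgn(3000, hurst = 0.5)
  expect_lt(abs(cor(y[-1], y[-length(y)])), 0.06)
  expect_error(rfgn(10, hurst = 1.5), "hurst")
})
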