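test_that("branch levels follow the fork-counting definition", {
  # soma with three primary unbranched dendrites: all level 1
  nd <- data.frame(id = 1:7, parent = c(NA, 1, 2, 1, 4, 1, 6),
                   kind = c("soma", rep("dendrite", 6)),
                   x = c(0, 1, 2, 0, 0, -1, -2), y = c(0, 0, 0, 1, 2, 0, 0),
                   z = 0, radius = 0.5)
  a <- assign_levels(arbor(nd))
  expect_equal(a$branches$level, c(1, 1, 1))

  # balanced binary tree: level counts 2^(i-1)
  h <- generate_htree(1.4, levels = 6, L1 = 50)
  b <- assign_levels(h)$branches
  expect_equal(as.vector(table(b$level)), 2^(0:5))
  expect_equal(max(b$level), 6)
})

test_that("log-log branch scaling slope matches analytic expectations", {
  # two levels, lengths 100 and 50, counts 1 and 2: slope exactly -1
  nd <- data.frame(id = 1:4, parent = c(NA, 1, 2, 2),
                   kind = c("soma", rep("dendrite", 3)),
                   x = c(0, 100, 100, 100), y = c(0, 0, 50, -50), z = 0,
                   radius = 0.5)
  st <- branch_length_stats(arbor(nd), n_bins = 2)
  expect_true(st$slope_defined)
  expect_equal(st$loglog_slope, -1, tolerance = 1e-9)

  # straight H-trees: slope equals -D_target exactly (one level per bin)
  for (D in c(1.2, 1.4, 1.6)) {
    h <- generate_htree(D, levels = 8, total_length = 1000)
    st <- branch_length_stats(h, n_bins = 8)
    expect_equal(st$loglog_slope, -D, tolerance = 1e-9)
  }

  # all-equal lengths: one occupied bin, slope flagged undefined
  e <- generate_equal_length_htree(90, levels = 4, total_length = 100)
  ste <- branch_length_stats(e)
  expect_false(ste$slope_defined)
  expect_true(is.na(ste$loglog_slope))
})

test_that("weave and fork angles are measured in [0, 180] with exact fixtures", {
  straight <- chain_arbor(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))
  expect_equal(measure_angles(straight)$weave$angle, c(0, 0), tolerance = 1e-7)

  bend <- chain_arbor(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(measure_angles(bend)$weave$angle, 90, tolerance = 1e-9)

  h <- generate_htree(1.4, levels = 5, L1 = 50)
  expect_true(all(abs(measure_angles(h)$fork$angle - 90) < 1e-6))
  expect_true(all(measure_angles(generate_toy_arbor(5, seed = 2))$weave$angle >= 0))
  expect_true(all(measure_angles(generate_toy_arbor(5, seed = 2))$weave$angle <= 180))
})

test_that("branch-length equalization preserves totals, topology and angles", {
  nd <- data.frame(id = 1:4, parent = c(NA, 1, 2, 2),
                   kind = c("soma", rep("dendrite", 3)),
                   x = c(0, 2, 6, 2), y = c(0, 0, 0, 6), z = 0, radius = 0.5)
  a <- arbor(nd) # branch lengths 2, 4, 6
  eq <- equalize_branch_lengths(a)
  be <- assign_levels(eq)$branches
  expect_equal(be$length, rep(4, 3), tolerance = 1e-9)
  expect_equal(sum(be$length), 12, tolerance = 1e-9)

  single <- cylinder_arbor(10, 0.5)
  eq1 <- equalize_branch_lengths(single)
  expect_equal(eq1$nodes$x, single$nodes$x, tolerance = 1e-9)

  # weave angles survive rescaling
  w <- generate_weaving_htree(1.4, levels = 4, total_length = 400,
                              weave_sigma = 20, seed = 4)
  th0 <- measure_angles(w)$weave$angle
  th1 <- measure_angles(equalize_branch_lengths(w))$weave$angle
  expect_equal(th1, th0, tolerance = 1e-6)
})

test_that("surface area uses midpoint subdivision with interior exclusion", {
  a1 <- cylinder_arbor(10, 0.5)
  m1 <- mesh_from_centerline(a1)
  # subdivision alone preserves area exactly; compare against raw mesh area
  expect_equal(surface_area(m1), fractalarbor:::mesh_area(m1), tolerance = 1e-9)
  expect_equal(surface_area(m1), 2 * pi * 0.5 * 10 + pi * 0.25, tolerance = 0.02)

  # a thin branch running inside a fat cylinder: the deep segment (all
  # vertices strictly interior) contributes nothing to A_s
  fat_thin <- arbor(data.frame(id = 1:4, parent = c(NA, 1, 2, 3),
                               kind = c("soma", rep("dendrite", 3)),
                               x = c(0, 10, 9, 3), y = 0, z = 0,
                               radius = c(1, 1, 0.2, 0.2)))
  mft <- mesh_from_centerline(fat_thin)
  raw <- fractalarbor:::mesh_area(mft)
  As <- surface_area(mft)
  deep_band <- 2 * pi * 0.2 * 6 # side area of the fully buried 9 -> 3 segment
  expect_lt(As, raw - 0.9 * deep_band)

  # independent point-in-cylinder oracle agrees with the C++ predicate on
  # the thin tube's vertices (fat cylinder axis: y = z = 0, x in (0, 10))
  S <- as.matrix(mft$segments[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  thin_faces <- which(mft$segments$radius[mft$segment_of_face] < 0.5)
  vidx <- unique(as.vector(mft$faces[thin_faces, ]))
  pts <- mft$vertices[vidx, , drop = FALSE]
  got <- fractalarbor:::points_in_segments_cpp(pts, integer(nrow(pts)), S)
  want <- sqrt(pts[, 2]^2 + pts[, 3]^2) < 1 - 1e-9 & pts[, 1] > 1e-9 &
    pts[, 1] < 10 - 1e-9
  expect_equal(as.logical(got), as.logical(want))

  # meshes without a segment mapping fall back to the raw area with a warning
  sp <- generate_sphere_mesh(5, 2)
  expect_warning(As <- surface_area(sp), "segment mapping")
  expect_equal(As, fractalarbor:::mesh_area(sp), tolerance = 1e-9)
})

test_that("convex hull metrics match closed forms and a brute-force oracle", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  hm <- hull_metrics(cube)
  expect_equal(hm$A_b, 6, tolerance = 1e-9)
  expect_equal(hm$V_b, 1, tolerance = 1e-9)

  set.seed(21)
  for (k in 1:5) {
    P <- matrix(rnorm(30), ncol = 3)
    got <- hull_metrics(P)
    want <- oracle_hull_small(P)
    expect_equal(got$A_b, want$area, tolerance = 1e-6)
    expect_equal(got$V_b, want$volume, tolerance = 1e-6)
  }

  # adding interior points never changes the hull
  P <- matrix(rnorm(300), ncol = 3)
  hull0 <- hull_metrics(P)
  inner <- P[sample(nrow(P), 50, replace = TRUE), ] * 0.2
  hull1 <- hull_metrics(rbind(P, inner))
  expect_equal(hull1$A_b, hull0$A_b, tolerance = 1e-9)
  expect_equal(hull1$V_b, hull0$V_b, tolerance = 1e-9)

  # coplanar input: degenerate flag, zero volume
  flat <- cbind(matrix(runif(40), ncol = 2), 0.5)
  hf <- hull_metrics(flat)
  expect_true(hf$degenerate)
  expect_equal(hf$V_b, 0)
})

test_that("model volume matches closed forms and counts overlaps once", {
  vm <- model_volume(cylinder_arbor(10, 1), 4)
  expect_equal(as.numeric(vm), 10 * pi, tolerance = 0.05)

  # two widely separated branches: volumes add
  two <- arbor(data.frame(id = 1:3, parent = c(NA, 1, 1),
                          kind = c("soma", "dendrite", "dendrite"),
                          x = c(0.03, 10.01, -9.99), y = 0.02, z = 0.01,
                          radius = 1))
  expect_equal(as.numeric(model_volume(two, 4)), 2 * 10 * pi, tolerance = 0.05)

  # overlapping branches count once
  overlap <- arbor(data.frame(id = 1:3, parent = c(NA, 1, 1),
                              kind = c("soma", "dendrite", "dendrite"),
                              x = c(0.03, 10.01, 10.01),
                              y = c(0.02, 0.02, 0.62), z = 0.01, radius = 1))
  expect_lt(as.numeric(model_volume(overlap, 4)), 2 * 10 * pi)

  # filled sphere: V_m / V_b = 1
  sp <- generate_sphere_mesh(10, 4)
  expect_equal(as.numeric(model_volume(sp, 4)) / hull_metrics(sp)$V_b, 1,
               tolerance = 0.02)
})

test_that("all morphometrics are invariant under rigid motion", {
  a <- generate_toy_arbor(n_levels = 5, seed = 9)
  b <- rotate_arbor(a, c(0.2, -1, 0.5), 71)
  b$nodes$x <- b$nodes$x + 13.7
  b$nodes$y <- b$nodes$y - 4.2

  ba <- assign_levels(a)$branches
  bb <- assign_levels(b)$branches
  expect_equal(bb$length, ba$length, tolerance = 1e-9)
  expect_equal(measure_angles(b)$weave$angle, measure_angles(a)$weave$angle,
               tolerance = 1e-6)
  expect_equal(measure_angles(b)$fork$angle, measure_angles(a)$fork$angle,
               tolerance = 1e-6)

  ma <- mesh_from_centerline(a)
  mb <- mesh_from_centerline(b)
  expect_equal(surface_area(mb), surface_area(ma), tolerance = 1e-4)
  ha <- hull_metrics(ma)
  hb <- hull_metrics(mb)
  expect_equal(hb$A_b, ha$A_b, tolerance = 1e-4)
  expect_equal(hb$V_b, ha$V_b, tolerance = 1e-4)
  expect_equal(as.numeric(model_volume(b, 4)), as.numeric(model_volume(a, 4)),
               tolerance = 0.02)
})
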