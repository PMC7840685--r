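test_that("centerline meshes follow the 16-ring/32-face/14-cap construction", {
  a1 <- cylinder_arbor(10, 0.5)
  m1 <- mesh_from_centerline(a1)
  expect_equal(nrow(m1$faces), 46) # 32 side faces + 14-face end cap
  expect_equal(length(unique(m1$segment_of_face)), 1)

  a2 <- chain_arbor(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  m2 <- mesh_from_centerline(a2)
  expect_equal(nrow(m2$faces), 64 + 14) # two segments, one cap

  # cylinder side area is close to the closed form 2*pi*r*l; the inscribed
  # 16-gon under-estimates the circumference by sin(pi/16)/(pi/16) = 0.64%
  # and the cap adds ~pi r^2
  expect_equal(fractalarbor:::mesh_area(m1), 2 * pi * 0.5 * 10 + pi * 0.25,
               tolerance = 0.02)

  # a fork: child branches start at the parent's final ring location
  y <- arbor(data.frame(id = 1:4, parent = c(NA, 1, 2, 2),
                        kind = c("soma", rep("dendrite", 3)),
                        x = c(0, 5, 10, 10), y = c(0, 0, 3, -3), z = 0,
                        radius = 0.5))
  my <- mesh_from_centerline(y)
  expect_equal(nrow(my$segments), 3)
  expect_equal(nrow(my$faces), 3 * 32 + 2 * 14)
})

test_that("meshing commutes with rigid rotation", {
  # the segment cylinders rotate exactly; ring vertices may twist about the
  # tube axis (the frame transport is reference-dependent), which no
  # downstream metric observes
  h <- generate_htree(1.4, levels = 4, L1 = 40)
  R <- fractalarbor:::.rotmat(c(1, 2, 3), 33)
  m_rot <- mesh_from_centerline(rotate_arbor(h, c(1, 2, 3), 33))
  m <- mesh_from_centerline(h)
  expect_equal(m_rot$faces, m$faces)
  S <- as.matrix(m$segments[, 1:6])
  S_rot <- as.matrix(m_rot$segments[, 1:6])
  expect_equal(S_rot, cbind(S[, 1:3] %*% t(R), S[, 4:6] %*% t(R)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m_rot$segments$radius, m$segments$radius, tolerance = 1e-12)
  expect_equal(fractalarbor:::mesh_area(m_rot), fractalarbor:::mesh_area(m),
               tolerance = 1e-9)
  # surface areas with interior exclusion agree to discretization twist
  expect_equal(surface_area(m_rot), surface_area(m), tolerance = 1e-4)
})

test_that("voxelization is exact and conservative", {
  # one small triangle inside a single voxel
  tri <- new_mesh <- fractalarbor:::new_mesh(
    rbind(c(0.1, 0.1, 0.1), c(0.2, 0.1, 0.1), c(0.1, 0.2, 0.1)),
    rbind(c(1, 2, 3)))
  g <- voxelize(tri, resolution = 1)
  expect_equal(nrow(g$coords), 1)

  # axis-aligned square spanning 2x2 voxels at 2 voxels/um
  sq <- fractalarbor:::new_mesh(
    rbind(c(0.01, 0.01, 0.2), c(0.99, 0.01, 0.2), c(0.99, 0.99, 0.2),
          c(0.01, 0.99, 0.2)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  g2 <- voxelize(sq, resolution = 2)
  expect_equal(nrow(g2$coords), 4)
  expect_error(voxelize(sq, resolution = -1), "resolution")

  # every mesh vertex's containing voxel is occupied
  sp <- generate_sphere_mesh(5, 2)
  gs <- voxelize(sp, 1)
  key <- function(cc, dims) cc[, 1] + dims[1] * (cc[, 2] + dims[2] * cc[, 3])
  vvox <- floor(sweep(sp$vertices, 2, gs$origin) / gs$side - 1e-12)
  vvox <- pmin(pmax(vvox, 0), matrix(gs$dims - 1L, nrow(vvox), 3, byrow = TRUE))
  expect_true(all(key(vvox, gs$dims) %in% key(gs$coords, gs$dims)))

  # doubling the resolution on a thin surface scales counts ~4x (area-like)
  n1 <- nrow(voxelize(sp, 2)$coords)
  n2 <- nrow(voxelize(sp, 4)$coords)
  expect_gt(n2 / n1, 3.2)
  expect_lt(n2 / n1, 4.8)
})

test_that("interior fill finds the enclosed volume of closed surfaces", {
  sp <- generate_sphere_mesh(6, 3)
  g <- voxelize(sp, 2, fill_interior = TRUE)
  gs <- voxelize(sp, 2, fill_interior = FALSE)
  n_int <- nrow(g$coords) - nrow(gs$coords)
  expect_gt(n_int, 0) # watertight: flood fill finds a nonempty interior
  # interior volume below the ball volume, cover above it
  expect_lt(n_int * g$side^3, 4 / 3 * pi * 6^3)
  expect_gt(nrow(g$coords) * g$side^3, 4 / 3 * pi * 6^3)
})
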