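# independent oracles and small fixture builders used across the suite

# brute-force sliding box count on a coordinate list (voxel units): enumerates
# every diagonal offset and counts occupied boxes on the shifted partition,
# with the same cube-intersects-box occupancy rule as the package
oracle_box_count <- function(coords, b_vox, step_vox = 1, max_offsets = 64) {
  noff <- min(max_offsets, max(1, ceiling(b_vox / step_vox - 1e-9)))
  counts <- sapply(seq_len(noff) - 1, function(o) {
    delta <- o * step_vox
    cells <- NULL
    for (i in seq_len(nrow(coords))) {
      lo <- floor((coords[i, ] + delta) / b_vox)
      hi <- floor((coords[i, ] + delta + 1 - 1e-9) / b_vox)
      g <- expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
      cells <- rbind(cells, as.matrix(g))
    }
    nrow(unique(cells))
  })
  min(counts)
}

# brute-force 3D convex hull for tiny point sets: every triple that has all
# other points strictly on one side is a supporting plane; area from those
# facets, volume from signed tetrahedra against the centroid
oracle_hull_small <- function(P) {
  n <- nrow(P)
  ctr <- colMeans(P)
  area <- 0
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c <- P[k, ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    if (sqrt(sum(nrm^2)) < 1e-12) next
    d <- as.matrix(sweep(P, 2, a)) %*% nrm
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      # outward orientation for the volume contribution
      if (sum((a - ctr) * nrm) < 0) nrm <- -nrm
      area <- area + 0.5 * sqrt(sum(nrm^2))
      vol <- vol + abs(sum((a - ctr) * nrm)) / 6
    }
  }
  list(area = area, volume = vol)
}

# unbranched cylinder arbor along x, generic offsets to avoid grid alignment
cylinder_arbor <- function(len = 10, radius = 0.5) {
  arbor(data.frame(id = 1:2, parent = c(NA, 1), kind = c("soma", "dendrite"),
                   x = c(0.03, 0.03 + len), y = 0.02, z = 0.01, radius = radius))
}

# straight chain with given node positions (first node is the soma)
chain_arbor <- function(pos, radius = 0.5) {
  pos <- as.matrix(pos)
  arbor(data.frame(id = seq_len(nrow(pos)),
                   parent = c(NA, seq_len(nrow(pos) - 1)),
                   kind = c("soma", rep("dendrite", nrow(pos) - 1)),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3], radius = radius))
}

# rigid rotation of an arbor about the origin
rotate_arbor <- function(x, axis, angle_deg) {
  R <- fractalarbor:::.rotmat(axis, angle_deg)
  pos <- as.matrix(x$nodes[, c("x", "y", "z")]) %*% t(R)
  x$nodes$x <- pos[, 1]
  x$nodes$y <- pos[, 2]
  x$nodes$z <- pos[, 3]
  x
}

# unit-cube OBJ text (8 vertices, 12 triangles)
write_cube_obj <- function(path, origin = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * side
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  writeLines(c(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  path
}
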