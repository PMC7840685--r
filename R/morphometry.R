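#' Branch length statistics and the log-log branch scaling slope
#'
#' Tabulates per-branch lengths relative to the longest branch and histograms
#' the number of branches N against \eqn{L/L_{max}} in log-spaced bins. The
#' least-squares slope of log10(N) on log10(L/L_max) over occupied bins is the
#' branch-length scaling exponent: for a straight H-tree it equals minus the
#' tree's scaling exponent D, while traced arbors show no well-defined slope.
#'
#' @param x an [arbor].
#' @param n_bins number of log-spaced bins (default 10). Using one bin per
#'   distinct level makes the H-tree slope exact.
#' @return A `branch_stats` list: `per_branch`, `hist` (bin centers and
#'   counts), `loglog_slope` (negative; `NA` with `slope_defined = FALSE` when
#'   fewer than two occupied bins).
#' @export
branch_length_stats <- function(x, n_bins = 10L) {
  x <- assign_levels(x)
  tab <- x$branches
  out <- list(per_branch = tab)
  lrel <- tab$L_rel
  rng <- range(log10(lrel))
  if (diff(rng) < 1e-12) {
    out$hist <- data.frame(center = 10^mean(rng), count = length(lrel))
    out$loglog_slope <- NA_real_
    out$slope_defined <- FALSE
  } else {
    edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1L)
    bin <- findInterval(log10(lrel), edges, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nbins = n_bins)
    centers <- 10^((edges[-1] + edges[-length(edges)]) / 2)
    # abscissa for the fit: geometric mean of the observed L/L_max in each bin
    # (bin centers drift off the occupied positions and would bias the slope)
    gmean <- vapply(seq_len(n_bins), function(b) {
      v <- lrel[bin == b]
      if (length(v)) 10^mean(log10(v)) else NA_real_
    }, numeric(1))
    out$hist <- data.frame(center = centers, L_gmean = gmean, count = cnt)
    occ <- cnt >= 1L
    if (sum(occ) < 2L) {
      out$loglog_slope <- NA_real_
      out$slope_defined <- FALSE
    } else {
      fit <- lm(log10(cnt[occ]) ~ log10(gmean[occ]))
      out$loglog_slope <- unname(coef(fit)[2])
      out$slope_defined <- TRUE
    }
  }
  class(out) <- "branch_stats"
  out
}

#' @export
print.branch_stats <- function(x, ...) {
  cat("<branch_stats> ", nrow(x$per_branch), " branches; log-log slope ",
      if (x$slope_defined) format(x$loglog_slope, digits = 4) else "undefined",
      "\n", sep = "")
  invisible(x)
}

#' Measure weave and fork angles of an arbor
#'
#' Weave angles theta are the angles between connecting segments along a
#' branch; the fork angle phi of a branch not emanating from the soma is the
#' angle between its first segment and the final segment of its parent branch.
#' All angles are measured via the arc cosine of the normalized dot product
#' and therefore folded into \[0, 180\] degrees: left and right deviations are
#' not distinguished.
#'
#' @param x an [arbor].
#' @return List of class `angle_set` with data.frames `weave` (`branch`,
#'   `index`, `angle`, rotation-plane normal `ax/ay/az`) and `fork` (`branch`,
#'   `angle`, `ax/ay/az`).
#' @export
measure_angles <- function(x) {
  br <- arbor_branches(x)
  pos <- as.matrix(x$nodes[, c("x", "y", "z")])
  weave <- list()
  fork <- list()
  for (b in seq_along(br)) {
    p <- br[[b]]$path
    P <- pos[p, , drop = FALSE]
    d <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
    ns <- nrow(d)
    if (ns >= 2) {
      for (k in seq_len(ns - 1)) {
        ang <- .vec_angle(d[k, ], d[k + 1, ])
        axv <- .cross3(d[k, ], d[k + 1, ])
        nn <- sqrt(sum(axv^2))
        axv <- if (nn > 1e-12) axv / nn else c(NA_real_, NA_real_, NA_real_)
        weave[[length(weave) + 1L]] <- c(b, k, ang, axv)
      }
    }
    pb <- br[[b]]$parent_branch
    if (!is.na(pb)) {
      pp <- br[[pb]]$path
      dpar <- pos[pp[length(pp)], ] - pos[pp[length(pp) - 1L], ]
      ang <- .vec_angle(dpar, d[1, ])
      axv <- .cross3(dpar, d[1, ])
      nn <- sqrt(sum(axv^2))
      axv <- if (nn > 1e-12) axv / nn else c(NA_real_, NA_real_, NA_real_)
      fork[[length(fork) + 1L]] <- c(b, ang, axv)
    }
  }
  weave <- if (length(weave)) {
    m <- do.call(rbind, weave)
    data.frame(branch = as.integer(m[, 1]), index = as.integer(m[, 2]),
               angle = m[, 3], ax = m[, 4], ay = m[, 5], az = m[, 6])
  } else data.frame(branch = integer(), index = integer(), angle = numeric(),
                    ax = numeric(), ay = numeric(), az = numeric())
  fork <- if (length(fork)) {
    m <- do.call(rbind, fork)
    data.frame(branch = as.integer(m[, 1]), angle = m[, 2],
               ax = m[, 3], ay = m[, 4], az = m[, 5])
  } else data.frame(branch = integer(), angle = numeric(),
                    ax = numeric(), ay = numeric(), az = numeric())
  structure(list(weave = weave, fork = fork), class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat("<angle_set> ", nrow(x$weave), " weave angles (median ",
      if (nrow(x$weave)) format(median(x$weave$angle), digits = 4) else "-",
      " deg), ", nrow(x$fork), " fork angles (median ",
      if (nrow(x$fork)) format(median(x$fork$angle), digits = 4) else "-",
      " deg)\n", sep = "")
  invisible(x)
}

#' Equalize branch lengths
#'
#' Rescales every branch along its own direction sequence to a common length,
#' preserving all weave and fork angles, and re-anchors each subtree at its
#' parent's displaced tip. With `preserve_total` the common length is the
#' total branch length divided by the branch count, so the combined length of
#' all branches matches the undistorted arbor; otherwise the median branch
#' length is used. Suppressing the length distribution this way removes the
#' short proximal branches of traced arbors and lowers their measured fractal
#' dimension.
#'
#' @param x an [arbor].
#' @param preserve_total keep the combined branch length unchanged (default).
#' @return An [arbor] with equal branch lengths.
#' @export
equalize_branch_lengths <- function(x, preserve_total = TRUE) {
  br <- arbor_branches(x)
  if (!length(br)) stop("arbor has no branches")
  lens <- vapply(br, `[[`, numeric(1), "length")
  target <- if (preserve_total) sum(lens) / length(lens) else median(lens)
  nd <- x$nodes
  pos <- as.matrix(nd[, c("x", "y", "z")])
  newpos <- pos
  # process branches so parents come before children
  ord <- order(vapply(br, `[[`, integer(1), "level"))
  for (b in ord) {
    p <- br[[b]]$path
    s <- target / lens[b]
    anchor_new <- newpos[p[1], ]
    d <- pos[p[-1], , drop = FALSE] - pos[p[-length(p)], , drop = FALSE]
    steps <- apply(d * s, 2, cumsum)
    if (length(p) == 2L) steps <- matrix(steps, nrow = 1)
    newpos[p[-1], ] <- sweep(steps, 2, anchor_new, "+")
  }
  nd$x <- newpos[, 1]; nd$y <- newpos[, 2]; nd$z <- newpos[, 3]
  out <- x
  out$nodes <- nd
  out
}

#' Model surface area with interior-face exclusion
#'
#' Computes the membrane surface area A_s of a centerline mesh. Precision is
#' raised by splitting each triangle into four midpoint sub-triangles (which
#' preserves total area exactly); a sub-face contributes nothing when all
#' three of its vertices lie strictly inside another segment's cylinder, so
#' buried faces at segment junctions are not counted. Ties (points exactly on
#' a cylinder surface or at its ends) count as outside.
#'
#' @param mesh an `arbor_mesh`. For meshes without a segment mapping (for
#'   example spheres or meshes read from OBJ) the subdivided raw area is
#'   returned with a warning.
#' @return A_s in square micrometres.
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "arbor_mesh"))
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  mAB <- (A + B) / 2
  mBC <- (B + C) / 2
  mCA <- (C + A) / 2
  # 4 sub-faces per face, vertex triplets stacked per sub-face
  subv <- list(list(A, mAB, mCA), list(B, mBC, mAB),
               list(C, mCA, mBC), list(mAB, mBC, mCA))
  tri_area <- function(a, b, c) {
    u <- b - a
    v <- c - a
    0.5 * sqrt((u[, 2] * v[, 3] - u[, 3] * v[, 2])^2 +
               (u[, 3] * v[, 1] - u[, 1] * v[, 3])^2 +
               (u[, 1] * v[, 2] - u[, 2] * v[, 1])^2)
  }
  areas <- lapply(subv, function(s) tri_area(s[[1]], s[[2]], s[[3]]))
  if (is.null(mesh$segments) || all(is.na(mesh$segment_of_face))) {
    warning("mesh has no segment mapping; returning raw (subdivided) mesh area")
    return(sum(unlist(areas)))
  }
  S <- as.matrix(mesh$segments[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  keep_total <- 0
  for (q in seq_along(subv)) {
    pts <- rbind(subv[[q]][[1]], subv[[q]][[2]], subv[[q]][[3]])
    forbid <- rep.int(mesh$segment_of_face, 3L)
    inside <- points_in_segments_cpp(pts, forbid, S)
    nf <- nrow(F)
    buried <- inside[seq_len(nf)] & inside[nf + seq_len(nf)] & inside[2L * nf + seq_len(nf)]
    keep_total <- keep_total + sum(areas[[q]][!buried])
  }
  keep_total
}

#' Convex-hull bounding area and volume
#'
#' The bounding area A_b and bounding volume V_b of an arbor are the facet
#' area and enclosed volume of the convex hull of its mesh vertices.
#'
#' @param points an n x 3 matrix of points, or an `arbor_mesh` (its vertices
#'   are used).
#' @return List with `A_b`, `V_b` (micrometres^2/^3) and `degenerate`. For
#'   coplanar input the volume is 0, `degenerate` is `TRUE`, and the area is
#'   that of the flattened hull counted on both sides.
#' @export
hull_metrics <- function(points) {
  if (inherits(points, "arbor_mesh")) points <- points$vertices
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points for a 3D hull")
  h <- convex_hull_cpp(points)
  if (!h$degenerate) {
    return(list(A_b = h$area, V_b = h$volume, degenerate = FALSE))
  }
  # coplanar fallback: 2D hull in the principal plane
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  uv <- sweep(points, 2, ctr) %*% sv$v[, 1:2]
  ch <- chull(uv)
  poly <- uv[ch, , drop = FALSE]
  n <- nrow(poly)
  area2d <- abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
                    poly[c(2:n, 1), 1] * poly[, 2])) / 2
  list(A_b = 2 * area2d, V_b = 0, degenerate = TRUE)
}

#' Branch volume from solid voxelization
#'
#' Measures the volume occupied by the branches on the voxel lattice;
#' overlapping segments are counted once (the union). A plain count of
#' covering voxels overestimates thin-tube volumes by a half-voxel skin, so
#' the boundary layer is resolved: for centerline meshes every voxel within a
#' tube radius of the surface cover contributes the fraction of its eight
#' sub-cell centers lying strictly inside the union of segment cylinders
#' (midpoint quadrature at twice the stated resolution). Meshes without
#' segment provenance (spheres, imported OBJ) are flood-filled from the grid
#' boundary and the surface cover enters with weight one half — the midpoint
#' of the inner fill and the outer cover.
#'
#' @param mesh a closed `arbor_mesh`, or an [arbor].
#' @param resolution voxels per micrometre (default 4).
#' @return V_m in cubic micrometres, with voxel counts as attributes.
#' @export
model_volume <- function(mesh, resolution = 4) {
  if (inherits(mesh, "arbor")) mesh <- mesh_from_centerline(mesh)
  has_segments <- !is.null(mesh$segments) && nrow(mesh$segments) > 0
  if (has_segments) {
    return(solid_volume_segments(mesh$segments, resolution))
  }
  g <- voxelize(mesh, resolution, fill_interior = FALSE)
  interior <- flood_interior_slabs(g$coords, g$dims)
  if (nrow(interior) == 0) {
    stop("no enclosed interior found: mesh is open (flood-fill leak) or the ",
         "resolution is too coarse for the branch width")
  }
  vm <- (nrow(interior) + nrow(g$coords) / 2) * g$side^3
  attr(vm, "n_interior") <- nrow(interior)
  attr(vm, "n_surface") <- nrow(g$coords)
  vm
}

# union volume of segment cylinders by strict center-in-cell counting on a
# lattice at twice the stated voxel resolution; each occupied half-resolution
# cell counts once however many cylinders cover it
solid_volume_segments <- function(segs, resolution) {
  h <- 1 / (2 * resolution)
  M <- 2^17 # key stride (exact in doubles up to ~2^53; axes stay below 2^17 cells)
  p0 <- as.matrix(segs[, c("x0", "y0", "z0")])
  p1 <- as.matrix(segs[, c("x1", "y1", "z1")])
  rr <- segs$radius
  gmin <- pmin(apply(p0, 2, min), apply(p1, 2, min)) - max(rr) - h
  keys <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    a <- p0[i, ]
    b <- p1[i, ]
    r <- rr[i]
    lo <- floor((pmin(a, b) - r - gmin) / h)
    hi <- ceiling((pmax(a, b) + r - gmin) / h)
    cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
    ctr <- sweep((cand + 0.5) * h, 2, gmin, "+")
    d <- b - a
    len2 <- sum(d^2)
    if (len2 <= 0) next
    w <- sweep(ctr, 2, a)
    t <- (w %*% d) / len2
    q <- w - t %*% t(d)
    inside <- t > 0 & t < 1 & rowSums(q^2) < r^2 * (1 - 1e-12)
    keys[[i]] <- cand[inside, 1] + M * (cand[inside, 2] + M * cand[inside, 3])
  }
  n <- length(unique(unlist(keys)))
  vm <- n * h^3
  attr(vm, "n_cells") <- n
  vm
}
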