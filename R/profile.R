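#' Dilate a voxel grid by a spherical spine layer
#'
#' Uniformly expands the voxelized arbor in every direction: the occupied set
#' becomes the union of Euclidean balls of the given radius around the
#' occupied voxel centers. The 2 um default models the layer around the
#' dendrites in which a spine could grow to form a synapse with a passing
#' axon; it assumes maximal spine density (a lower density can be modelled by
#' a profile pre-factor, which rescales P without affecting comparisons).
#'
#' @param grid a [voxel_grid] (1 voxel/um for the profile analysis).
#' @param radius dilation radius in micrometres (default 2).
#' @return A [voxel_grid], padded so all coordinates remain non-negative.
#' @export
dilate_grid <- function(grid, radius = 2) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius < 0) stop("parameter error: radius must be >= 0")
  rv <- radius / grid$side
  k <- floor(rv)
  off <- as.matrix(expand.grid(x = -k:k, y = -k:k, z = -k:k))
  off <- off[rowSums(off^2) <= rv^2 + 1e-9, , drop = FALSE]
  if (nrow(off) == 1L) return(grid)
  pad <- as.integer(k)
  cc <- grid$coords
  n <- nrow(cc)
  all_c <- matrix(0L, n * nrow(off), 3)
  for (j in seq_len(nrow(off))) {
    all_c[(j - 1L) * n + seq_len(n), ] <- cc + matrix(off[j, ], n, 3, byrow = TRUE)
  }
  all_c <- all_c + pad
  dims <- grid$dims + 2L * pad
  key <- all_c[, 1] + as.numeric(dims[1]) * (all_c[, 2] + as.numeric(dims[2]) * all_c[, 3])
  all_c <- all_c[!duplicated(key), , drop = FALSE]
  voxel_grid(all_c, grid$resolution, grid$origin - pad * grid$side, dims)
}

#' Fibonacci-lattice viewpoint directions
#'
#' Near-uniform unit vectors on the sphere by the golden-angle spiral:
#' latitudes uniform in (-1, 1), azimuths stepping by the golden angle. 201
#' viewpoints suffice for profile averages (within 1 percent of the converged
#' value); 10001 are used for visualization maps.
#'
#' @param n number of directions (>= 1).
#' @return An n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  n <- as.integer(n)
  if (n < 1) stop("parameter error: n must be >= 1")
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(x = r * cos(k * ga), y = r * sin(k * ga), z = z)
}

#' Projected (shadow) area of a voxel grid from one direction
#'
#' The occupied voxel centers are rotated so the view direction maps onto the
#' projection axis, orthographically projected, rounded onto a lattice of one
#' voxel-side spacing anchored at the rotated centroid, and de-duplicated:
#' voxels hiding behind one another block each other and count once. Each
#' remaining lattice cell contributes one cell area.
#'
#' @param grid a [voxel_grid] (1 voxel/um in the standard protocol).
#' @param direction view direction (3-vector, need not be unit).
#' @return Projected area P in square micrometres.
#' @export
project_area <- function(grid, direction) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (sqrt(sum(direction^2)) < 1e-12) stop("parameter error: zero direction")
  pts <- (grid$coords + 0.5) * grid$side
  project_count_cpp(pts, matrix(direction / sqrt(sum(direction^2)), 1),
                    grid$side)[1] * grid$side^2
}

#' Orientation-averaged connectivity profile
#'
#' Computes the profile P (total projected area of the arbor's branches,
#' including any dilated spine layer already present in the grid) for each
#' viewpoint and averages arithmetically, emulating axons arriving from every
#' direction. P normalized by the arbor surface area A_s measures connectivity
#' per operating cost (P/A_s > 1 is possible, since the spine layer is in P
#' but not in A_s); P normalized by the bounding area A_b is the connectivity
#' density.
#'
#' @param grid a [voxel_grid].
#' @param viewpoints matrix of directions from [fibonacci_directions]
#'   (default 201).
#' @param A_s,A_b optional surface/bounding areas used to fill the ratios.
#' @param density spine-density pre-factor in (0, 1] scaling every profile;
#'   the default 1 models a solid (maximally dense) spine layer. Comparisons
#'   across arbors of one type share the factor, so it cancels there.
#' @return A `profile_result`: per-direction `P`, `mean_P`, `argmax`
#'   direction, and `P_over_As`, `P_over_Ab` when the areas are given.
#' @export
mean_profile <- function(grid, viewpoints = fibonacci_directions(201),
                         A_s = NULL, A_b = NULL, density = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  viewpoints <- as.matrix(viewpoints)
  if (nrow(viewpoints) < 1) stop("parameter error: empty viewpoint set")
  if (!(density > 0 && density <= 1)) {
    stop("parameter error: density must be in (0, 1]")
  }
  pts <- (grid$coords + 0.5) * grid$side
  P <- project_count_cpp(pts, viewpoints, grid$side) * grid$side^2 * density
  out <- list(directions = viewpoints, P = P, mean_P = mean(P),
              argmax = viewpoints[which.max(P), ],
              P_over_As = if (!is.null(A_s)) mean(P) / A_s else NA_real_,
              P_over_Ab = if (!is.null(A_b)) mean(P) / A_b else NA_real_)
  class(out) <- "profile_result"
  out
}

#' @export
print.profile_result <- function(x, ...) {
  cat("<profile_result> mean P = ", format(x$mean_P, digits = 6), " um^2 over ",
      nrow(x$directions), " viewpoints (range ",
      format(min(x$P), digits = 5), "-", format(max(x$P), digits = 5), ")\n",
      sep = "")
  if (!is.na(x$P_over_As)) cat("  P/A_s = ", format(x$P_over_As, digits = 4), "\n", sep = "")
  if (!is.na(x$P_over_Ab)) cat("  P/A_b = ", format(x$P_over_Ab, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Profile sphere map
#'
#' Per-direction profile over a dense viewpoint lattice, for plotting profile
#' spheres; the argmax direction marks the orientation of maximal exposure
#' (for CA1 neurons, typically the direction of incoming Schaffer-collateral
#' axons).
#'
#' @param grid a [voxel_grid].
#' @param n number of viewpoints (default 10001).
#' @return data.frame `dir_x, dir_y, dir_z, P_um2` with attribute `argmax`.
#' @export
profile_sphere_map <- function(grid, n = 10001L) {
  dirs <- fibonacci_directions(n)
  pr <- mean_profile(grid, dirs)
  out <- data.frame(dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
                    P_um2 = pr$P)
  attr(out, "argmax") <- pr$argmax
  out
}
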