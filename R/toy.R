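#' Generate a toy neuron-like arbor
#'
#' A random binary tree whose angle and size statistics are anchored to the
#' median morphometrics of traced CA1 pyramidal-cell arbors: weave angles
#' theta (median 12 degrees, half-normal), fork angles phi (median 37 degrees,
#' folded normal), log-normal segment lengths (median 2.4 um) and branch
#' widths (median 1.4 um). Only the medians are anchored; the full joint
#' distribution of real arbors is not modelled. Generation is a pure function
#' of the arguments and seed.
#'
#' @param n_levels number of branch levels; `n_levels = 1` gives unbranched
#'   primary paths.
#' @param theta_median median weave angle, degrees.
#' @param phi_median median fork angle, degrees.
#' @param segment_length_median median segment length, micrometres.
#' @param width_median median branch width, micrometres.
#' @param n_primary number of primary branches leaving the soma (basal arbors
#'   have several).
#' @param segments_per_branch_median median number of segments per branch.
#' @param seed integer seed.
#' @return An [arbor].
#' @export
generate_toy_arbor <- function(n_levels = 7L, theta_median = 12,
                               phi_median = 37, segment_length_median = 2.4,
                               width_median = 1.4, n_primary = 3L,
                               segments_per_branch_median = 8L, seed = 1L) {
  stopifnot(n_levels >= 1, theta_median > 0, theta_median < 180,
            phi_median > 0, phi_median < 180,
            segment_length_median > 0, width_median > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  theta_sd <- theta_median / qnorm(0.75) # half-normal with the stated median
  nodes <- new.env()
  nodes$N <- 1L
  nodes$tab <- list(list(pos = c(0, 0, 0), parent = NA_integer_,
                         kind = "soma", radius = width_median / 2))
  add_node <- function(pos, parent, radius) {
    nodes$N <- nodes$N + 1L
    nodes$tab[[nodes$N]] <- list(pos = pos, parent = parent,
                                 kind = "dendrite", radius = radius)
    nodes$N
  }
  grow_branch <- function(attach_node, pos, dir, level) {
    wid <- rlnorm(1, log(width_median), 0.3)
    nseg <- max(2L, as.integer(round(rlnorm(1, log(segments_per_branch_median), 0.4))))
    parent <- attach_node
    for (k in seq_len(nseg)) {
      len <- rlnorm(1, log(segment_length_median), 0.4)
      pos <- pos + len * dir
      parent <- add_node(pos, parent, wid / 2)
      if (k < nseg) {
        th <- abs(rnorm(1, 0, theta_sd))
        ax <- c(.rotmat(dir, runif(1, 0, 360)) %*% .perp(dir))
        dir <- c(.rotmat(ax, th) %*% dir)
      }
    }
    if (level < n_levels) {
      psi <- runif(1, 0, 360)
      for (k in 1:2) {
        phi <- fold_angle(abs(rnorm(1, phi_median, 12)))
        ax <- c(.rotmat(dir, psi + (k - 1) * 180 + rnorm(1, 0, 15)) %*% .perp(dir))
        cdir <- c(.rotmat(ax, phi) %*% dir)
        grow_branch(parent, pos, cdir, level + 1L)
      }
    }
  }
  for (p in seq_len(n_primary)) {
    dir <- .unit(rnorm(3))
    grow_branch(1L, c(0, 0, 0), dir, 1L)
  }
  tab <- nodes$tab[seq_len(nodes$N)]
  pos <- do.call(rbind, lapply(tab, `[[`, "pos"))
  arbor(data.frame(id = seq_along(tab),
                   parent = vapply(tab, `[[`, integer(1), "parent"),
                   kind = vapply(tab, `[[`, character(1), "kind"),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   radius = vapply(tab, `[[`, numeric(1), "radius")))
}

#' Icosphere mesh
#'
#' Closed triangulated sphere by recursive icosahedron subdivision; the
#' Euclidean reference fixture with dimension 3. At `refinement = 4` the
#' surface area is within about 0.2 percent of \eqn{4\pi r^2}.
#'
#' @param radius sphere radius, micrometres.
#' @param refinement number of 4-fold subdivision passes.
#' @return An `arbor_mesh` (no centerline segments).
#' @export
generate_sphere_mesh <- function(radius = 10, refinement = 4L) {
  if (!(radius > 0)) stop("parameter error: radius must be > 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  V <- V / sqrt(rowSums(V^2))
  for (it in seq_len(refinement)) {
    mid <- new.env()
    nv <- nrow(V)
    Vl <- lapply(seq_len(nv), function(i) V[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      i <- mid[[key]]
      if (!is.null(i)) return(i)
      m <- .unit(Vl[[a]] + Vl[[b]])
      Vl[[length(Vl) + 1L]] <<- m
      mid[[key]] <- length(Vl)
      length(Vl)
    }
    Fn <- matrix(0L, 4 * nrow(F), 3)
    r <- 0L
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c0 <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c0); ca <- midpoint(c0, a)
      Fn[r + 1L, ] <- c(a, ab, ca)
      Fn[r + 2L, ] <- c(b, bc, ab)
      Fn[r + 3L, ] <- c(c0, ca, bc)
      Fn[r + 4L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    V <- do.call(rbind, Vl)
    F <- Fn
  }
  new_mesh(V * radius, F, rep(NA_integer_, nrow(F)))
}
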