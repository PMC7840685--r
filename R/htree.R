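#' H-tree generators
#'
#' H-trees are binary fractal trees whose branch lengths shrink geometrically
#' between levels following \deqn{L_i = L_1 / 2^{(i-1)/D},} where \eqn{L_i} is
#' the branch length of the i-th level and \eqn{D} the target scaling
#' exponent. The level-i branch count is \eqn{2^{i-1}}. Fork angles are 90
#' degrees (each child perpendicular to its parent); three-dimensional trees
#' rotate the branching plane by 90 degrees about the parent axis at each
#' level, so successive levels cycle through the coordinate axes.
#'
#' When `total_length` is given instead of `L1`, the first-branch length is
#' chosen so the total length of all branches equals it — held constant across
#' `D` values, as in the comparative analyses this generator supports. The
#' default total length of 9000 um sizes the trees so that the first-branch
#' length L1 (the H-tree's maximal branch length) falls in the 109-352 um
#' range of maximal branch lengths reported for traced CA1 arbors across the
#' scaling exponents of interest, which keeps the box-counting scaling window
#' (2 um to a fifth of the bounding box) comfortably wider than one decade.
#'
#' @param D_target scaling exponent (> 0).
#' @param levels number of branch levels (default 12).
#' @param L1 first-branch length in micrometres (exclusive with
#'   `total_length`).
#' @param total_length total branch length in micrometres; the default 9000 um
#'   is used when neither argument is supplied.
#' @param width branch width W in micrometres (cylinder diameter; default 1).
#' @param dimensionality `"3D"` (branching plane rotates between levels) or
#'   `"2D"` (planar tree).
#' @return An [arbor] whose root is a degenerate soma node at the origin.
#' @examples
#' h <- generate_htree(1.4, levels = 3, L1 = 100)
#' assign_levels(h)$branches
#' @export
generate_htree <- function(D_target, levels = 12L, L1 = NULL, total_length = NULL,
                           width = 1, dimensionality = c("3D", "2D")) {
  build_htree(D_target, levels, L1, total_length, width,
              match.arg(dimensionality), phi = 90, equal_lengths = FALSE,
              weave_sigma = 0, hurst = 0.75, segment_length = width, seed = NULL)
}

#' Weaving H-tree generator
#'
#' As [generate_htree], but every branch is subdivided into short segments
#' (default length equal to the branch width) and bent at each internal
#' junction by weave angles drawn from a fractional Gaussian noise sequence
#' rescaled to standard deviation `weave_sigma`. Weaving bends but does not
#' stretch: the arc length of each branch is preserved exactly, and child
#' branches keep their nominal H-tree orientation while attaching at the
#' displaced parent tip. The measured box-count dimension increases with
#' `weave_sigma` at fixed `D_target`.
#'
#' @inheritParams generate_htree
#' @param weave_sigma standard deviation of the weave-angle distribution,
#'   degrees (> 0).
#' @param hurst Hurst exponent of the fractional Gaussian noise, in (0, 1).
#'   The weave-noise protocol specifies self-similar noise but not its Hurst
#'   exponent; 0.75 is this package's documented default.
#' @param segment_length subdivision length in micrometres (default: `width`).
#' @param seed integer seed; generation is a pure function of the arguments.
#' @export
generate_weaving_htree <- function(D_target, levels = 12L, L1 = NULL,
                                   total_length = NULL, width = 1,
                                   dimensionality = c("3D", "2D"),
                                   weave_sigma = 10, hurst = 0.75,
                                   segment_length = width, seed = 1L) {
  if (weave_sigma < 0) stop("parameter error: weave_sigma must be >= 0")
  if (!(hurst > 0 && hurst < 1)) stop("parameter error: hurst must be in (0,1)")
  dimensionality <- match.arg(dimensionality)
  if (weave_sigma == 0) { # zero-noise limit: exactly the straight H-tree
    return(generate_htree(D_target, levels, L1, total_length, width,
                          dimensionality))
  }
  build_htree(D_target, levels, L1, total_length, width,
              dimensionality, phi = 90, equal_lengths = FALSE,
              weave_sigma = weave_sigma, hurst = hurst,
              segment_length = segment_length, seed = seed)
}

#' Equal-branch-length H-tree
#'
#' All branches share one common length (`total_length` divided by the branch
#' count) and the forking angle is set to `phi`: the construction used to ask
#' what remains of fractal scaling once the branch-length distribution is
#' suppressed. At `phi = 90` with the standard total length the branches
#' collapse onto a compact, nearly solid structure whose box-count dimension
#' approaches 3; at the neurons' median fork angle (37 degrees) the tree
#' retains limited-range fractal behavior.
#'
#' @param phi fork angle in degrees, in (0, 180].
#' @inheritParams generate_htree
#' @export
generate_equal_length_htree <- function(phi = 90, levels = 12L,
                                        total_length = 9000, width = 1,
                                        dimensionality = c("3D", "2D")) {
  if (!(phi > 0 && phi <= 180)) stop("parameter error: phi must be in (0, 180]")
  build_htree(D_target = 1, levels = levels, L1 = NULL,
              total_length = total_length, width = width,
              match.arg(dimensionality), phi = phi, equal_lengths = TRUE,
              weave_sigma = 0, hurst = 0.75, segment_length = width, seed = NULL)
}

#' Equalize the branch lengths of an existing H-tree (or any arbor)
#'
#' Convenience wrapper around [equalize_branch_lengths] with the total length
#' preserved.
#'
#' @param x an [arbor].
#' @export
equalize_htree <- function(x) equalize_branch_lengths(x, preserve_total = TRUE)

build_htree <- function(D_target, levels, L1, total_length, width,
                        dimensionality, phi, equal_lengths,
                        weave_sigma, hurst, segment_length, seed) {
  levels <- as.integer(levels)
  if (levels < 1) stop("parameter error: levels must be >= 1")
  if (!(D_target > 0)) stop("parameter error: D_target must be > 0")
  if (!(width > 0)) stop("parameter error: width must be > 0")
  if (!is.null(L1) && !is.null(total_length)) {
    stop("specify exactly one of L1 and total_length")
  }
  if (is.null(L1) && is.null(total_length)) total_length <- 9000
  if (equal_lengths) {
    nb <- 2^levels - 1
    if (is.null(total_length)) total_length <- L1 * nb
    lens <- rep(total_length / nb, levels)
  } else {
    scale_i <- 2^(-(seq_len(levels) - 1) / D_target)
    if (is.null(L1)) {
      L1 <- total_length / sum(2^(seq_len(levels) - 1) * scale_i)
    }
    lens <- L1 * scale_i
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  three_d <- dimensionality == "3D"
  r <- width / 2
  # node accumulators (grown geometrically)
  N <- 1L
  cap <- 1024L
  px <- numeric(cap); py <- numeric(cap); pz <- numeric(cap)
  pr <- numeric(cap); pp <- integer(cap)
  px[1] <- 0; py[1] <- 0; pz[1] <- 0; pr[1] <- r; pp[1] <- NA_integer_
  add_node <- function(pos, parent) {
    if (N + 1L > cap) {
      cap <<- cap * 2L
      length(px) <<- cap; length(py) <<- cap; length(pz) <<- cap
      length(pr) <<- cap; length(pp) <<- cap
    }
    N <<- N + 1L
    px[N] <<- pos[1]; py[N] <<- pos[2]; pz[N] <<- pos[3]
    pr[N] <<- r; pp[N] <<- parent
    N
  }
  # queue of branches: (attach node, start pos, direction, plane normal, level)
  queue <- list(list(node = 1L, pos = c(0, 0, 0), dir = c(1, 0, 0),
                     nrm = c(0, 0, 1), level = 1L))
  while (length(queue)) {
    b <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    L <- lens[b$level]
    if (weave_sigma > 0) {
      m <- max(2L, as.integer(round(L / segment_length)))
      ang <- rfgn(m - 1L, hurst)
      if (m - 1L >= 2L) {
        s <- sd(ang)
        ang <- if (is.finite(s) && s > 0) ang / s * weave_sigma else rep(0, m - 1L)
      } else {
        ang <- ang * weave_sigma # single junction: population (unit-variance) scaling
      }
      d <- b$dir
      pos <- b$pos
      parent <- b$node
      step <- L / m
      for (k in seq_len(m)) {
        pos <- pos + step * d
        parent <- add_node(pos, parent)
        if (k < m) d <- c(.rotmat(b$nrm, ang[k]) %*% d)
      }
      tip_node <- parent
      tip_pos <- pos
    } else {
      tip_pos <- b$pos + L * b$dir
      tip_node <- add_node(tip_pos, b$node)
    }
    if (b$level < levels) {
      for (sgn in c(1, -1)) {
        cd <- c(.rotmat(b$nrm, sgn * phi) %*% b$dir)
        if (three_d) {
          # branching plane rotates 90 degrees about the parent axis per
          # level: the child's plane normal is the parent direction projected
          # perpendicular to the child direction
          cn <- b$dir - sum(b$dir * cd) * cd
          child_nrm <- if (sqrt(sum(cn^2)) > 1e-9) .unit(cn) else .perp(cd)
        } else {
          child_nrm <- b$nrm
        }
        queue[[length(queue) + 1L]] <- list(node = tip_node, pos = tip_pos,
                                            dir = cd, nrm = child_nrm,
                                            level = b$level + 1L)
      }
    }
  }
  nodes <- data.frame(id = seq_len(N), parent = pp[seq_len(N)],
                      kind = c("soma", rep("dendrite", N - 1L)),
                      x = px[seq_len(N)], y = py[seq_len(N)], z = pz[seq_len(N)],
                      radius = pr[seq_len(N)])
  arbor(nodes)
}

#' Fractional Gaussian noise
#'
#' Exact simulation of stationary fractional Gaussian noise (the increment
#' process of fractional Brownian motion) by the Durbin-Levinson recursion,
#' with unit variance. Used to draw self-similar weave-angle sequences for
#' weaving H-trees.
#'
#' @param n sequence length.
#' @param hurst Hurst exponent in (0, 1); 0.5 gives white noise.
#' @return Numeric vector of length `n`.
#' @export
rfgn <- function(n, hurst = 0.75) {
  if (!(hurst > 0 && hurst < 1)) stop("parameter error: hurst must be in (0,1)")
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (n == 1L) return(rnorm(1))
  H2 <- 2 * hurst
  gam <- 0.5 * (abs(seq_len(n))^H2 - 2 * abs(seq_len(n) - 1)^H2 +
                abs(seq_len(n) - 2)^H2) # gamma(0), gamma(1), ...
  X <- numeric(n)
  X[1] <- rnorm(1)
  phi <- gam[2] / gam[1]
  v <- gam[1] * (1 - phi^2)
  X[2] <- phi * X[1] + sqrt(v) * rnorm(1)
  if (n > 2) {
    for (t in 2:(n - 1)) {
      kap <- (gam[t + 1] - sum(phi * gam[t:2])) / v
      phi <- c(phi - kap * rev(phi), kap)
      v <- v * (1 - kap^2)
      X[t + 1] <- sum(phi * X[t:1]) + sqrt(max(v, 0)) * rnorm(1)
    }
  }
  X
}
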