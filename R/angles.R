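#' Fold an angle into the measurement range
#'
#' Measured branch angles do not distinguish left from right of the reference
#' axis, so raw angles above 180 degrees are folded back: `fold_angle(200)`
#' is 160. Values above 360 (which cannot arise for multipliers up to 2 on
#' angles up to 180) are reduced modulo 360 with a warning.
#'
#' @param raw angle(s) in degrees, >= 0.
#' @return Angle(s) in \[0, 180\].
#' @examples
#' fold_angle(c(90, 180, 200)) # 90 180 160
#' @export
fold_angle <- function(raw) {
  if (any(raw < 0)) stop("parameter error: raw angle must be >= 0")
  if (any(raw > 360)) {
    warning("angle(s) above 360 degrees clamped")
    raw <- raw %% 360
  }
  ifelse(raw > 180, 360 - raw, raw)
}

#' Scale weave and/or fork angles by a multiplier
#'
#' Produces a distorted arbor in which every targeted junction angle theta (or
#' phi) is multiplied by `alpha`. Junctions are processed starting with the
#' angles furthest from the soma and working inwards; at each junction the
#' entire connected section between that angle and the terminal tips is
#' rotated rigidly in the plane of the two direction vectors that define the
#' angle (a rotation quaternion about their cross product), so segment lengths
#' and all downstream angles are preserved exactly. Angles whose raw scaled
#' value exceeds 180 degrees are measured folded (see [fold_angle]); the
#' number of such crossings is reported as an attribute. Branch
#' self-intersections created by the distortion are permitted (they are rare
#' below `alpha = 2`) and a proximity-based count is attached.
#'
#' @param x an [arbor].
#' @param alpha multiplier in \[0, 2\].
#' @param target `"weave"`, `"fork"`, or `"both"`.
#' @return The distorted [arbor], with attributes `n_folded` (junctions whose
#'   scaled angle exceeded 180) and `n_intersections` (segment midpoints lying
#'   inside another, non-adjacent branch's cylinder).
#' @export
scale_angles <- function(x, alpha, target = c("weave", "fork", "both")) {
  target <- match.arg(target)
  if (alpha < 0) stop("parameter error: alpha must be >= 0")
  if (alpha > 2) stop("parameter error: alpha must be <= 2")
  br <- arbor_branches(x)
  nd <- x$nodes
  pos <- as.matrix(nd[, c("x", "y", "z")])
  n <- nrow(nd)
  pidx <- match(nd$parent, nd$id)
  kids <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  # path length from soma to each node (original geometry; rotations are isometries)
  seglen <- sqrt(rowSums((pos - pos[ifelse(is.na(pidx), 1L, pidx), , drop = FALSE])^2))
  seglen[is.na(pidx)] <- 0
  dist <- numeric(n)
  ord_nodes <- order(vapply(seq_len(n), function(i) {
    d <- 0L; j <- i
    while (!is.na(pidx[j])) { d <- d + 1L; j <- pidx[j] }
    d
  }, integer(1)))
  for (i in ord_nodes) if (!is.na(pidx[i])) dist[i] <- dist[pidx[i]] + seglen[i]
  # preorder with subtree intervals: descendants of i are contiguous in `seq`
  seq_pre <- integer(n)
  tin <- integer(n)
  tout <- integer(n)
  stack <- arbor_root(x)
  timer <- 0L
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (i > 0L) {
      timer <- timer + 1L
      seq_pre[timer] <- i
      tin[i] <- timer
      stack <- c(stack, -i, kids[[i]])
    } else {
      tout[-i] <- timer
    }
  }
  descendants <- function(i) {
    if (tout[i] <= tin[i]) integer(0) else seq_pre[(tin[i] + 1L):tout[i]]
  }
  # junction list: each is (kind, node defining the rotation pivot, in-node,
  # out-node, subtree root(s) to rotate)
  jn <- list()
  for (b in seq_along(br)) {
    p <- br[[b]]$path
    if (target %in% c("weave", "both") && length(p) >= 3) {
      for (k in 2:(length(p) - 1L)) {
        jn[[length(jn) + 1L]] <- list(pivot = p[k], a = p[k - 1L], c = p[k + 1L],
                                      sub = p[k], dist = dist[p[k]])
      }
    }
    pb <- br[[b]]$parent_branch
    if (target %in% c("fork", "both") && !is.na(pb)) {
      pp <- br[[pb]]$path
      jn[[length(jn) + 1L]] <- list(pivot = p[1L], a = pp[length(pp) - 1L],
                                    c = p[2L], sub = p[2L], dist = dist[p[1L]])
    }
  }
  if (length(jn)) {
    ordj <- order(-vapply(jn, `[[`, numeric(1), "dist"),
                  vapply(jn, `[[`, integer(1), "pivot"))
    n_folded <- 0L
    for (q in ordj) {
      j <- jn[[q]]
      v_in <- pos[j$pivot, ] - pos[j$a, ]
      v_out <- pos[j$c, ] - pos[j$pivot, ]
      th <- .vec_angle(v_in, v_out)
      if (th < 1e-9 || th > 180 - 1e-9) next # rotation plane undefined
      if (alpha * th > 180) n_folded <- n_folded + 1L
      axis <- .cross3(v_in, v_out)
      R <- .rotmat(axis, (alpha - 1) * th)
      rot_set <- if (j$sub == j$pivot) descendants(j$pivot) else
        c(j$sub, descendants(j$sub))
      pv <- pos[j$pivot, ]
      pos[rot_set, ] <- sweep(sweep(pos[rot_set, , drop = FALSE], 2, pv) %*% t(R),
                              2, pv, "+")
    }
  } else n_folded <- 0L
  nd$x <- pos[, 1]; nd$y <- pos[, 2]; nd$z <- pos[, 3]
  out <- x
  out$nodes <- nd
  attr(out, "n_folded") <- n_folded
  attr(out, "n_intersections") <- count_intersections(out)
  out
}

# crude self-intersection count: segment midpoints inside another branch's
# cylinder (non-adjacent branches only)
count_intersections <- function(x) {
  segs <- arbor_segments(x)
  if (is.null(segs) || nrow(segs) < 2) return(0L)
  mids <- cbind((segs$x0 + segs$x1) / 2, (segs$y0 + segs$y1) / 2,
                (segs$z0 + segs$z1) / 2)
  S <- as.matrix(segs[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  inside <- points_in_segments_cpp(mids, seq_len(nrow(S)), S)
  sum(inside)
}

#' Generate a set of angle-manipulated arbor variants
#'
#' One variant per (alpha, target) combination, each derived independently
#' from the unmodified arbor.
#'
#' @param x an [arbor].
#' @param alphas numeric vector of multipliers in \[0, 2\] (the standard grid
#'   is 0 to 2 in steps of 0.25).
#' @param targets character vector from `"weave"`, `"fork"`, `"both"`.
#' @return A list of lists `(alpha, target, arbor)`.
#' @export
generate_variant_set <- function(x, alphas = seq(0, 2, by = 0.25),
                                 targets = "weave") {
  out <- list()
  for (tg in targets) for (a in alphas) {
    out[[length(out) + 1L]] <- list(alpha = a, target = tg,
                                    arbor = scale_angles(x, a, tg))
  }
  out
}
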