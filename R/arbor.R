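#' Centerline arbor objects
#'
#' An `arbor` is a rooted tree of tapered cylindrical segments in micrometre
#' coordinates: the canonical representation of a dendritic arbor centerline
#' (or of a synthetic H-tree). It is stored as a node table in SWC order; all
#' derived structure (branches, levels, segment cylinders) is computed from it.
#'
#' Branches follow the usual morphometric convention: a branch is the maximal
#' unbranched path between the soma (or a fork) and the next fork or terminal
#' tip, its length \eqn{L} is the sum of its segment lengths, and its level
#' \eqn{i} is 1 for branches emerging from the soma, 2 for branches emerging
#' from the first forks, and so on.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `parent`
#'   (integer id or `NA` for the single root), `kind` (`"soma"` or
#'   `"dendrite"`), `x`, `y`, `z` (micrometres) and `radius` (micrometres;
#'   half the branch width `W`).
#' @return An object of class `arbor`.
#' @examples
#' a <- arbor(data.frame(id = 1:3, parent = c(NA, 1, 2), kind = "dendrite",
#'                       x = c(0, 1, 2), y = 0, z = 0, radius = 0.7))
#' arbor_branches(a)
#' @export
arbor <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "parent", "kind", "x", "y", "z", "radius")
  if (!all(need %in% names(nodes))) {
    stop("nodes must have columns: ", paste(need, collapse = ", "))
  }
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  x <- structure(list(nodes = nodes), class = "arbor")
  validate_arbor(x)
  x
}

validate_arbor <- function(x) {
  nd <- x$nodes
  if (nrow(nd) == 0) stop("arbor has no nodes")
  if (anyDuplicated(nd$id)) stop("structure error: duplicate node ids")
  root <- which(is.na(nd$parent))
  if (length(root) != 1) {
    stop("structure error: arbor must have exactly one root, found ", length(root))
  }
  pidx <- match(nd$parent, nd$id)
  bad <- which(!is.na(nd$parent) & is.na(pidx))
  if (length(bad)) {
    stop("structure error: node ", nd$id[bad[1]], " references absent parent ",
         nd$parent[bad[1]])
  }
  if (!all(nd$kind %in% c("soma", "dendrite"))) {
    stop("node kind must be 'soma' or 'dendrite'")
  }
  if (any(nd$kind == "dendrite" & !(nd$radius > 0))) {
    stop("dendrite nodes must have radius > 0")
  }
  # acyclicity/connectivity: every node must reach the root
  depth <- rep(NA_integer_, nrow(nd))
  depth[root] <- 0L
  pending <- TRUE
  while (pending) {
    newd <- depth[pidx] + 1L
    fill <- is.na(depth) & !is.na(newd)
    pending <- any(fill)
    depth[fill] <- newd[fill]
  }
  if (anyNA(depth)) {
    stop("structure error: arbor contains a cycle or disconnected nodes")
  }
  invisible(x)
}

arbor_root <- function(x) which(is.na(x$nodes$parent))

#' Decompose an arbor into branches
#'
#' @param x an [arbor].
#' @return A list with one element per branch: `path` (row indices of the node
#'   table, beginning at the anchoring soma/fork node), `level`, `length`
#'   (micrometres) and `parent_branch` (index or `NA`).
#' @export
arbor_branches <- function(x) {
  nd <- x$nodes
  n <- nrow(nd)
  pidx <- match(nd$parent, nd$id)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  }
  nkids <- lengths(kids)
  soma <- nd$kind == "soma"
  if (any(soma & !is.na(pidx) & !soma[ifelse(is.na(pidx), 1L, pidx)])) {
    stop("structure error: soma node attached to a dendrite")
  }
  root <- arbor_root(x)
  # branch start edges: from soma nodes or fork nodes (or the root) into dendrites
  branches <- list()
  # queue of (anchor node, first node, level, parent branch)
  queue <- list()
  for (i in seq_len(n)) {
    anchor_like <- soma[i] || i == root
    if (anchor_like) {
      for (ch in kids[[i]]) if (!soma[ch]) {
        queue[[length(queue) + 1L]] <- list(anchor = i, first = ch, level = 1L,
                                            parent_branch = NA_integer_)
      }
    }
  }
  pos <- as.matrix(nd[, c("x", "y", "z")])
  while (length(queue)) {
    q <- queue[[1L]]
    queue[[1L]] <- NULL
    path <- c(q$anchor, q$first)
    cur <- q$first
    while (nkids[cur] == 1L && !soma[kids[[cur]][1L]]) {
      cur <- kids[[cur]][1L]
      path <- c(path, cur)
    }
    seglen <- sqrt(rowSums((pos[path[-1], , drop = FALSE] -
                            pos[path[-length(path)], , drop = FALSE])^2))
    bidx <- length(branches) + 1L
    branches[[bidx]] <- list(path = path, level = q$level, length = sum(seglen),
                             parent_branch = q$parent_branch)
    if (nkids[cur] >= 2L) {
      for (ch in kids[[cur]]) {
        queue[[length(queue) + 1L]] <- list(anchor = cur, first = ch,
                                            level = q$level + 1L,
                                            parent_branch = bidx)
      }
    }
  }
  branches
}

#' Branch levels and lengths of an arbor
#'
#' Assigns the branch level `i` (1 for branches emerging from the soma, 2 for
#' branches emerging from the first forks, ...) and tabulates branch lengths.
#'
#' @param x an [arbor].
#' @return The arbor with a `branches` data.frame component
#'   (`branch`, `level`, `length`, `L_rel`, `parent_branch`), where `L_rel`
#'   is \eqn{L/L_{max}}.
#' @export
assign_levels <- function(x) {
  br <- arbor_branches(x)
  if (length(br) == 0) stop("structure error: arbor has no branches")
  tab <- data.frame(branch = seq_along(br),
                    level = vapply(br, `[[`, integer(1), "level"),
                    length = vapply(br, `[[`, numeric(1), "length"),
                    parent_branch = vapply(br, `[[`, integer(1), "parent_branch"))
  tab$L_rel <- tab$length / max(tab$length)
  x$branches <- tab
  x
}

#' @export
print.arbor <- function(x, ...) {
  nd <- x$nodes
  br <- tryCatch(arbor_branches(x), error = function(e) NULL)
  cat("<arbor> ", nrow(nd), " nodes (", sum(nd$kind == "soma"), " soma), ",
      if (is.null(br)) "?" else length(br), " branches\n", sep = "")
  if (!is.null(br) && length(br)) {
    lv <- vapply(br, `[[`, integer(1), "level")
    ln <- vapply(br, `[[`, numeric(1), "length")
    cat("  levels 1..", max(lv), "; total branch length ",
        format(sum(ln), digits = 6), " um; L_max ",
        format(max(ln), digits = 6), " um\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.arbor <- function(object, ...) {
  object <- assign_levels(object)
  ang <- measure_angles(object)
  out <- list(n_nodes = nrow(object$nodes),
              n_branches = nrow(object$branches),
              levels = range(object$branches$level),
              total_length = sum(object$branches$length),
              L_max = max(object$branches$length),
              median_theta = if (nrow(ang$weave)) median(ang$weave$angle) else NA_real_,
              median_phi = if (nrow(ang$fork)) median(ang$fork$angle) else NA_real_,
              median_width = 2 * median(object$nodes$radius[object$nodes$kind == "dendrite"]))
  class(out) <- "summary.arbor"
  out
}

#' @export
print.summary.arbor <- function(x, ...) {
  cat("Arbor morphometry\n")
  cat("  nodes:        ", x$n_nodes, "\n")
  cat("  branches:     ", x$n_branches, " (levels ", x$levels[1], "-", x$levels[2], ")\n", sep = "")
  cat("  total length: ", format(x$total_length, digits = 6), " um\n", sep = "")
  cat("  L_max:        ", format(x$L_max, digits = 6), " um\n", sep = "")
  cat("  median theta: ", format(x$median_theta, digits = 4), " deg\n", sep = "")
  cat("  median phi:   ", format(x$median_phi, digits = 4), " deg\n", sep = "")
  cat("  median width: ", format(x$median_width, digits = 4), " um\n", sep = "")
  invisible(x)
}

#' @export
plot.arbor <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
  nd <- x$nodes
  pidx <- match(nd$parent, nd$id)
  ok <- !is.na(pidx)
  plot(nd[[ax[1]]], nd[[ax[2]]], type = "n", asp = 1,
       xlab = paste0(ax[1], " (um)"), ylab = paste0(ax[2], " (um)"), ...)
  segments(nd[[ax[1]]][pidx[ok]], nd[[ax[2]]][pidx[ok]],
           nd[[ax[1]]][ok], nd[[ax[2]]][ok])
  invisible(x)
}

#' Read a centerline arbor from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`); type 1 is soma, all
#' other types are treated as dendrite. Consecutive duplicate samples
#' (zero-length segments, a common tracing artifact) are merged. Soma samples
#' are kept but excluded from branch statistics by the downstream functions.
#'
#' @param path file path.
#' @return An [arbor].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("parse error: no data lines in ", path)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop("parse error: line ", idx[bad[1]], " has ", lengths(fields)[bad[1]],
         " fields (expected 7)")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    badln <- idx[which(rowSums(is.na(m)) > 0)[1]]
    stop("parse error: non-numeric field on line ", badln)
  }
  nodes <- data.frame(id = as.integer(m[, 1]),
                      parent = ifelse(m[, 7] < 0, NA_integer_, as.integer(m[, 7])),
                      kind = ifelse(m[, 2] == 1, "soma", "dendrite"),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6])
  nodes <- drop_zero_length(nodes)
  arbor(nodes)
}

# merge nodes coincident with their parent (zero-length segments)
drop_zero_length <- function(nodes) {
  repeat {
    pidx <- match(nodes$parent, nodes$id)
    d <- sqrt((nodes$x - nodes$x[pidx])^2 + (nodes$y - nodes$y[pidx])^2 +
              (nodes$z - nodes$z[pidx])^2)
    dup <- which(!is.na(d) & d < 1e-9 & nodes$kind == nodes$kind[pidx])
    if (!length(dup)) return(nodes)
    i <- dup[1]
    nodes$parent[!is.na(nodes$parent) & nodes$parent == nodes$id[i]] <- nodes$parent[i]
    nodes <- nodes[-i, ]
  }
}

#' Write an arbor to an SWC file
#'
#' @param x an [arbor]; soma nodes are written as SWC type 1, dendrites as
#'   type 3.
#' @param path output file path.
#' @export
write_swc <- function(x, path) {
  stopifnot(inherits(x, "arbor"))
  nd <- x$nodes
  if (nrow(nd) == 0) stop("refusing to write an empty arbor")
  type <- ifelse(nd$kind == "soma", 1L, 3L)
  parent <- ifelse(is.na(nd$parent), -1L, nd$parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by fractalarbor", con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     nd$id, type, nd$x, nd$y, nd$z, nd$radius, parent), con)
  invisible(path)
}

# segment table of an arbor: one row per parent->child dendrite edge
arbor_segments <- function(x) {
  br <- arbor_branches(x)
  nd <- x$nodes
  pos <- as.matrix(nd[, c("x", "y", "z")])
  out <- list()
  for (b in seq_along(br)) {
    p <- br[[b]]$path
    ns <- length(p) - 1L
    out[[b]] <- data.frame(x0 = pos[p[-length(p)], 1], y0 = pos[p[-length(p)], 2],
                           z0 = pos[p[-length(p)], 3],
                           x1 = pos[p[-1], 1], y1 = pos[p[-1], 2], z1 = pos[p[-1], 3],
                           radius = nd$radius[p[-1]],
                           branch = b, level = br[[b]]$level)
  }
  do.call(rbind, out)
}
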