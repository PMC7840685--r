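#' Read a triangle mesh from a Wavefront OBJ file
#'
#' Parses `v` and `f` records; polygonal faces with more than three vertices
#' are fan-triangulated. Texture/normal references (`f 1/2/3` forms) are
#' accepted and stripped.
#'
#' @param path file path.
#' @return An `arbor_mesh`: list with `vertices` (n x 3 matrix, micrometres),
#'   `faces` (m x 3 integer matrix, 1-based) and `segment_of_face`
#'   (`NA` for meshes without centerline provenance).
#' @export
read_obj_mesh <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (!length(vlines) || !length(flines)) {
    stop("format error: OBJ file needs v and f records")
  }
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                             function(s) as.numeric(s[1:3])))
  faces <- list()
  for (fl in flines) {
    toks <- strsplit(trimws(sub("^f", "", fl)), "\\s+")[[1]]
    vi <- as.integer(sub("/.*$", "", toks))
    if (anyNA(vi)) stop("format error: unparseable face record: ", fl)
    if (any(vi < 1 | vi > nrow(V))) {
      stop("format error: face index out of range in: ", fl)
    }
    if (length(vi) < 3) stop("format error: face with <3 vertices: ", fl)
    for (k in 2:(length(vi) - 1)) {
      faces[[length(faces) + 1L]] <- c(vi[1], vi[k], vi[k + 1])
    }
  }
  new_mesh(V, do.call(rbind, faces), rep(NA_integer_, length(faces)))
}

#' Write a triangle mesh to a Wavefront OBJ file
#'
#' @param mesh an `arbor_mesh`.
#' @param path output file path.
#' @export
write_obj_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "arbor_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

new_mesh <- function(vertices, faces, segment_of_face = NULL, segments = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(faces < 1 | faces > nrow(vertices))) {
    stop("format error: face index out of range")
  }
  structure(list(vertices = vertices, faces = faces,
                 segment_of_face = segment_of_face, segments = segments),
            class = "arbor_mesh")
}

#' @export
print.arbor_mesh <- function(x, ...) {
  cat("<arbor_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces), " faces",
      if (!is.null(x$segments)) paste0(", ", nrow(x$segments), " segments"),
      "\n", sep = "")
  invisible(x)
}

# raw triangle area sum
mesh_area <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}
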