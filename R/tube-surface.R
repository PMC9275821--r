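#' Tube surface objects
#'
#' A `tube_surface` is an oriented triangle mesh of a topological cylinder
#' (two boundary loops) or a closed surface (zero boundary loops), together
#' with an optional per-vertex cylinder chart `(s, phi)`: `s` is the
#' longitudinal coordinate in micrometres from the anterior end and `phi`
#' the circumferential coordinate in radians, periodic on `[0, 2*pi)`.
#' Faces are oriented so that face normals point inward, toward the lumen;
#' with that convention the mean curvature of a cylinder is positive.
#'
#' @param vertices numeric matrix, `n x 3`, vertex positions in micrometres.
#' @param faces integer matrix, `m x 3`, 1-based triangle vertex indices.
#' @param chart optional tibble with columns `vertex_id`, `s`, `phi`
#'   (one row per vertex).
#' @return An object of class `tube_surface`.
#' @export
tube_surface <- function(vertices, faces, chart = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  if (!is.null(chart)) {
    chart <- tibble::as_tibble(chart)
    stopifnot(all(c("vertex_id", "s", "phi") %in% names(chart)))
    chart <- chart[order(chart$vertex_id), , drop = FALSE]
    if (nrow(chart) != nrow(vertices)) {
      stop("chart must have one row per vertex")
    }
  }
  structure(
    list(vertices = vertices, faces = faces, chart = chart),
    class = "tube_surface"
  )
}

#' @export
print.tube_surface <- function(x, ...) {
  nb <- length(boundary_loops(x))
  cat(
    sprintf(
      "<tube_surface> %d vertices, %d faces, %d boundary loop(s), chart: %s\n",
      nrow(x$vertices), nrow(x$faces), nb,
      if (is.null(x$chart)) "none" else "(s, phi)"
    )
  )
  invisible(x)
}

#' Time sequence of tube surfaces with Lagrangian vertex correspondence
#'
#' All surfaces share vertex identity: vertex `i` is the same material point
#' at every timepoint, so velocities are plain finite differences of vertex
#' positions. Timestamps are in minutes.
#'
#' @param surfaces list of [tube_surface()] objects with equal vertex counts.
#' @param time numeric vector of timestamps (min), strictly increasing.
#' @return An object of class `surface_sequence`.
#' @export
surface_sequence <- function(surfaces, time) {
  stopifnot(length(surfaces) == length(time), length(time) >= 1)
  if (length(time) > 1 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  nv <- vapply(surfaces, function(s) nrow(s$vertices), integer(1))
  if (length(unique(nv)) != 1) stop("all surfaces must share vertex identity (equal vertex counts)")
  structure(list(surfaces = surfaces, time = as.numeric(time)),
            class = "surface_sequence")
}

#' @export
print.surface_sequence <- function(x, ...) {
  cat(sprintf("<surface_sequence> %d timepoints over [%g, %g] min, %d vertices\n",
              length(x$time), min(x$time), max(x$time),
              nrow(x$surfaces[[1]]$vertices)))
  invisible(x)
}

#' @export
length.surface_sequence <- function(x) length(x$time)

# Edges of each face as a 3m x 2 matrix (i, j) in face order.
face_edges <- function(faces) {
  rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
}

#' Boundary loops of a mesh
#'
#' Boundary edges are those that belong to exactly one face. Returns each
#' loop as an ordered integer vector of vertex ids.
#'
#' @param surface a [tube_surface()].
#' @return list of integer vectors (possibly empty).
#' @export
boundary_loops <- function(surface) {
  ed <- face_edges(surface$faces)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  if (length(bkey) == 0) return(list())
  bedges <- ed[key %in% bkey, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(as.character(bedges[, 1]),
                                         as.character(bedges[, 2])),
                                   directed = FALSE)
  comps <- igraph::components(g)
  lapply(seq_len(comps$no), function(k) {
    ids <- as.integer(igraph::V(g)$name[comps$membership == k])
    sub <- igraph::induced_subgraph(g, as.character(ids))
    # order around the loop
    path <- igraph::dfs(sub, root = 1)$order
    as.integer(igraph::V(sub)$name[path])
  })
}

# Per-face geometric quantities used throughout: corner positions, normals,
# areas. Faces oriented so cross(e1, e2) points inward.
face_geometry <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- sqrt(rowSums(cr^2))
  area <- nrm / 2
  list(p1 = p1, p2 = p2, p3 = p3,
       normal = cr / pmax(nrm, .Machine$double.eps),
       area = area)
}

#' Per-face and per-vertex areas
#'
#' @param surface a [tube_surface()].
#' @return `face_areas()` returns a numeric vector of triangle areas;
#'   `vertex_areas()` the barycentric vertex areas (one third of each
#'   incident triangle).
#' @export
face_areas <- function(surface) face_geometry(surface)$area

#' @rdname face_areas
#' @export
vertex_areas <- function(surface) {
  fa <- face_areas(surface)
  n <- nrow(surface$vertices)
  a <- numeric(n)
  f <- surface$faces
  for (k in 1:3) {
    acc <- tapply(fa / 3, f[, k], sum)
    idx <- as.integer(names(acc))
    a[idx] <- a[idx] + as.numeric(acc)
  }
  a
}

#' Per-vertex unit normals (inward)
#'
#' Area-weighted average of incident face normals, normalized. With the
#' package's face orientation convention these point toward the lumen.
#'
#' @param surface a [tube_surface()].
#' @return `n x 3` matrix of unit vectors.
#' @export
vertex_normals <- function(surface) {
  fg <- face_geometry(surface)
  f <- surface$faces
  n <- nrow(surface$vertices)
  acc <- matrix(0, n, 3)
  w <- fg$normal * fg$area
  for (k in 1:3) {
    for (d in 1:3) {
      s <- tapply(w[, d], f[, k], sum)
      idx <- as.integer(names(s))
      acc[idx, d] <- acc[idx, d] + as.numeric(s)
    }
  }
  len <- sqrt(rowSums(acc^2))
  acc / pmax(len, .Machine$double.eps)
}

# Vertices lying on a boundary edge.
boundary_vertices <- function(surface) {
  unique(unlist(boundary_loops(surface)))
}
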