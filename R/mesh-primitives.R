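#' Structured tube meshes
#'
#' Build a triangulated surface of revolution around an arbitrary polyline
#' of ring centers, with the package's inward-normal face orientation and a
#' per-vertex `(s, phi)` chart. `mesh_cylinder()` is the straight special
#' case; `mesh_torus_segment()` bends the tube along a circular arc.
#'
#' @param radius tube radius in micrometres; scalar or one value per ring.
#' @param length cylinder length in micrometres.
#' @param n_s number of rings along the tube (>= 2).
#' @param n_phi number of vertices per ring (>= 3).
#' @return A [tube_surface()] with chart attached.
#' @export
mesh_cylinder <- function(radius, length, n_s = 64, n_phi = 32) {
  s <- seq(0, length, length.out = n_s)
  centers <- cbind(0, 0, s)
  r <- rep_len(radius, n_s)
  e1 <- matrix(rep(c(1, 0, 0), each = n_s), n_s)
  e2 <- matrix(rep(c(0, 1, 0), each = n_s), n_s)
  mesh_tube_frames(centers, e1, e2, r, s, n_phi)
}

#' @rdname mesh_cylinder
#' @param rho centerline radius of the arc (micrometres).
#' @param angle arc angle in radians (e.g. `pi/2` for a quarter torus).
#' @export
mesh_torus_segment <- function(rho, radius, angle = pi / 2, n_s = 64, n_phi = 32) {
  th <- seq(0, angle, length.out = n_s)
  centers <- cbind(rho * cos(th), rho * sin(th), 0)
  e1 <- cbind(cos(th), sin(th), 0)            # radial, in-plane
  e2 <- matrix(rep(c(0, 0, 1), each = n_s), n_s)
  mesh_tube_frames(centers, e1, e2, rep_len(radius, n_s), rho * th, n_phi)
}

# Generic structured tube: ring centers (n_s x 3), per-ring orthonormal frame
# vectors e1, e2 spanning the cross-section plane, per-ring radius, and the
# chart coordinate s per ring. Faces oriented for inward normals.
mesh_tube_frames <- function(centers, e1, e2, radius, s, n_phi) {
  n_s <- nrow(centers)
  stopifnot(n_s >= 2, n_phi >= 3)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[1:n_phi]
  cph <- cos(phi); sph <- sin(phi)
  verts <- matrix(0, n_s * n_phi, 3)
  for (i in seq_len(n_s)) {
    idx <- (i - 1) * n_phi + seq_len(n_phi)
    verts[idx, ] <- matrix(centers[i, ], n_phi, 3, byrow = TRUE) +
      radius[i] * (outer(cph, e1[i, ]) + outer(sph, e2[i, ]))
  }
  faces <- structured_tube_faces(n_s, n_phi)
  chart <- tibble::tibble(
    vertex_id = seq_len(n_s * n_phi),
    s = rep(s, each = n_phi),
    phi = rep(phi, n_s)
  )
  tube_surface(verts, faces, chart)
}

# Triangulation of an n_s x n_phi vertex grid, periodic in phi, oriented so
# face normals point toward the tube axis (inward).
structured_tube_faces <- function(n_s, n_phi) {
  i <- rep(seq_len(n_s - 1), each = n_phi)
  j <- rep(seq_len(n_phi), n_s - 1)
  jp <- ifelse(j == n_phi, 1L, j + 1L)
  a <- (i - 1L) * n_phi + j
  b <- (i - 1L) * n_phi + jp
  c <- i * n_phi + j
  d <- i * n_phi + jp
  rbind(cbind(a, d, b), cbind(a, c, d))
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere of radius `R`, oriented for
#' inward normals.
#'
#' @param R radius (micrometres).
#' @param subdiv number of 4-to-1 subdivision passes (3 gives 1280 faces).
#' @param center sphere center.
#' @return A [tube_surface()] (closed; no chart).
#' @export
mesh_icosphere <- function(R = 1, subdiv = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (pass in seq_len(subdiv)) {
    nf <- nrow(f)
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mids <- new.env()
    newv <- list()
    midpoint <- function(i, j) {
      k <- key(i, j)
      got <- mids[[k]]
      if (!is.null(got)) return(got)
      newv[[length(newv) + 1]] <<- (v[i, ] + v[j, ]) / 2
      id <- nrow(v) + length(newv)
      mids[[k]] <- id
      id
    }
    f2 <- matrix(0L, nf * 4, 3)
    for (q in seq_len(nf)) {
      a <- f[q, 1]; b <- f[q, 2]; cc <- f[q, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      f2[(q - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- f2
  }
  v <- v / sqrt(rowSums(v^2)) * R
  # orient for inward normals: flip faces whose normal points away from center
  p1 <- v[f[, 1], ]; p2 <- v[f[, 2], ]; p3 <- v[f[, 3], ]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cent <- (p1 + p2 + p3) / 3
  flip <- rowSums(cr * cent) > 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  v <- v + matrix(center, nrow(v), 3, byrow = TRUE)
  tube_surface(v, f)
}
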