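# Core discrete differential geometry on tube_surface meshes: cotangent
# Laplacian, mean curvature, areas, enclosed volume, centerline, harmonic
# cylinder chart, and per-face tangent frames.

# Sparse cotangent weight matrix W (symmetric, zero diagonal) and the
# Laplacian L = W - diag(rowSums(W)), so (L %*% f)_i = sum_j w_ij (f_j - f_i).
cotan_laplacian <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  fg <- face_geometry(surface)
  bad <- which(fg$area < 1e-12)
  if (length(bad) > 0) {
    stop("degenerate (zero-area) triangles at face indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    dt / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
  }
  # angle at corner k weights the opposite edge
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  w <- c(cot_at(f[, 3], f[, 1], f[, 2]),
         cot_at(f[, 1], f[, 2], f[, 3]),
         cot_at(f[, 2], f[, 3], f[, 1])) / 2
  n <- nrow(v)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w), dims = c(n, n))
  L <- W - Matrix::Diagonal(n, Matrix::rowSums(W))
  list(W = W, L = L)
}

#' Mean curvature from the mesh Laplacian
#'
#' Applies the cotangent Laplace-Beltrami operator to the vertex positions;
#' the mean-curvature normal satisfies `Delta X = 2 H n` and is projected on
#' the inward vertex normal and halved. With inward normals, `H > 0` on a
#' cylinder (`H = 1/(2R)`) and `H < 0` in sharp neck regions whose axial
#' curvature exceeds the circumferential one. The one-ring stencil is
#' incomplete on boundary vertices; there the value is replaced by the mean
#' over adjacent interior vertices.
#'
#' @param surface a [tube_surface()].
#' @return numeric vector of per-vertex mean curvature (1/micrometre).
#' @export
mean_curvature <- function(surface) {
  lap <- cotan_laplacian(surface)
  A <- mixed_vertex_areas(surface)
  K <- as.matrix(lap$L %*% surface$vertices) / (2 * A)
  nrm <- vertex_normals(surface)
  H <- rowSums(K * nrm)
  bv <- boundary_vertices(surface)
  if (length(bv) > 0) {
    interior <- setdiff(seq_len(nrow(surface$vertices)), bv)
    Wl <- lap$W
    for (b in bv) {
      nb <- setdiff(which(Wl[b, ] != 0), bv)
      H[b] <- if (length(nb) > 0) mean(H[nb]) else NA_real_
    }
  }
  H
}

# Meyer mixed vertex areas: Voronoi area within non-obtuse triangles,
# T/2 at the obtuse corner and T/4 elsewhere in obtuse ones. Pairs with the
# cotangent Laplacian for pointwise-accurate curvature at irregular vertices.
mixed_vertex_areas <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  n <- nrow(v)
  A <- numeric(n)
  fa <- face_areas(surface)
  corn <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  # squared edge lengths opposite each corner
  d2 <- function(i, j) rowSums((v[f[, i], , drop = FALSE] - v[f[, j], , drop = FALSE])^2)
  l2 <- cbind(d2(2, 3), d2(3, 1), d2(1, 2))  # opposite corners 1,2,3
  cot <- matrix(0, nrow(f), 3)
  for (k in 1:3) {
    o <- corn[[k]]
    # cot of angle at corner k: (b^2 + c^2 - a^2) / (4 * area)
    cot[, k] <- (l2[, o[2]] + l2[, o[3]] - l2[, o[1]]) / (4 * fa)
  }
  obtuse_any <- cot[, 1] < 0 | cot[, 2] < 0 | cot[, 3] < 0
  for (k in 1:3) {
    o <- corn[[k]]
    vor <- (l2[, o[2]] * cot[, o[2]] + l2[, o[3]] * cot[, o[3]]) / 8
    contrib <- ifelse(obtuse_any, ifelse(cot[, k] < 0, fa / 2, fa / 4), vor)
    acc <- tapply(contrib, f[, k], sum)
    idx <- as.integer(names(acc))
    A[idx] <- A[idx] + as.numeric(acc)
  }
  A
}

#' Total surface area
#'
#' @param surface a [tube_surface()].
#' @return area in square micrometres.
#' @export
surface_area <- function(surface) sum(face_areas(surface))

#' Enclosed volume
#'
#' Boundary loops (if any) are capped by fan triangulation to their
#' centroids, using the winding opposite the adjacent boundary-face edges so
#' the closed mesh is consistently oriented; the volume then follows from
#' the divergence theorem.
#'
#' @param surface a [tube_surface()].
#' @return volume in cubic micrometres (positive).
#' @export
enclosed_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  loops <- boundary_loops(surface)
  if (length(loops) > 0) {
    # directed boundary edges in face winding order
    ed <- face_edges(f)
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    tab <- table(key)
    bdir <- ed[key %in% names(tab)[tab == 1L], , drop = FALSE]
    for (lp in loops) {
      if (length(lp) < 3) stop("open boundary loop cannot be capped")
      cen <- colMeans(v[lp, , drop = FALSE])
      v <- rbind(v, cen)
      ci <- nrow(v)
      sel <- bdir[, 1] %in% lp
      f <- rbind(f, cbind(bdir[sel, 2], bdir[sel, 1], ci))
    }
  }
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  vol <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
             p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
             p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  abs(vol)
}

#' Centerline from chart hoops
#'
#' Vertices are binned into `n_hoops` equal-width bands of the chart
#' coordinate `s`; the mean 3D position of each band is a centerline point,
#' and consecutive points are joined into a polyline.
#'
#' @param surface a [tube_surface()] with chart.
#' @param n_hoops number of constant-`s` bands (default 100).
#' @return A tibble of class `tube_centerline` with columns `hoop`, `s_mid`,
#'   `x`, `y`, `z`; total polyline length in attribute `"length"`.
#' @export
centerline <- function(surface, n_hoops = 100) {
  if (is.null(surface$chart)) stop("surface has no chart; run harmonic_cylinder_chart() first")
  stopifnot(n_hoops >= 2)
  s <- surface$chart$s
  br <- seq(min(s), max(s), length.out = n_hoops + 1)
  bin <- pmin(findInterval(s, br, rightmost.closed = TRUE), n_hoops)
  cnt <- tabulate(bin, n_hoops)
  if (any(cnt == 0)) {
    stop("empty hoop bin(s): ", paste(utils::head(which(cnt == 0), 5), collapse = ", "),
         "; use a coarser n_hoops")
  }
  pts <- rowsum(surface$vertices, bin) / cnt
  len <- sum(sqrt(rowSums(diff(pts)^2)))
  out <- tibble::tibble(
    hoop = seq_len(n_hoops),
    s_mid = (br[-1] + br[-(n_hoops + 1)]) / 2,
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
  attr(out, "length") <- len
  class(out) <- c("tube_centerline", class(out))
  out
}

#' Harmonic cylinder chart
#'
#' Computes a `(s, phi)` chart on a bare topological cylinder: `s` solves
#' the Laplace equation with the two boundary loops held at 0 and 1, and
#' `phi` is a harmonic angle with a prescribed period of `2*pi` across a
#' cut path joining the two loops, so it winds exactly once around every
#' hoop. This harmonic flattening serves as the isotropy-reference chart
#' for shear measurements.
#'
#' @param surface a [tube_surface()]; any existing chart is ignored.
#' @return the surface with a new chart (`s` in `[0, 1]`, `phi` in
#'   `[0, 2*pi)`).
#' @export
harmonic_cylinder_chart <- function(surface) {
  loops <- boundary_loops(surface)
  if (length(loops) != 2) {
    chi <- nrow(surface$vertices) - nrow(unique_edges(surface$faces)) + nrow(surface$faces)
    stop(sprintf(
      "mesh is not a topological cylinder: %d boundary loop(s), Euler characteristic %d",
      length(loops), chi))
  }
  n <- nrow(surface$vertices)
  lap <- cotan_laplacian(surface)
  L <- lap$L
  # --- s: Dirichlet 0/1 on the two loops
  fixed <- c(loops[[1]], loops[[2]])
  fval <- c(rep(0, length(loops[[1]])), rep(1, length(loops[[2]])))
  s <- solve_dirichlet(L, fixed, fval, n)
  # --- phi: harmonic with a 2*pi period across a cut path
  cut <- cut_path(surface, loops)
  sides <- cut_sides(surface, cut)
  # fold a 2*pi jump into the RHS: phi on side-2 copies = phi + 2*pi.
  # Build offsets per (face corner): edges from a side-2 face to a cut vertex
  # see the vertex at +2*pi. Equivalent elimination: solve L phi = b where
  # b accumulates -w_ij * 2*pi for edges crossing the cut.
  jump <- cut_jump_rhs(surface, lap$W, cut, sides)
  phi <- solve_fixed_one(L, jump$rhs, anchor = cut[1], n = n)
  phi <- phi %% (2 * pi)
  surface$chart <- tibble::tibble(vertex_id = seq_len(n), s = s, phi = phi)
  surface
}

unique_edges <- function(faces) {
  ed <- face_edges(faces)
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique(ed)
}

solve_dirichlet <- function(L, fixed, fval, n) {
  free <- setdiff(seq_len(n), fixed)
  x <- numeric(n)
  x[fixed] <- fval
  if (length(free) > 0) {
    A <- L[free, free, drop = FALSE]
    b <- -L[free, fixed, drop = FALSE] %*% fval
    x[free] <- as.numeric(Matrix::solve(A, b))
  }
  x
}

# shortest edge path between the two boundary loops (by Euclidean length)
cut_path <- function(surface, loops) {
  ed <- unique_edges(surface$faces)
  w <- sqrt(rowSums((surface$vertices[ed[, 1], , drop = FALSE] -
                     surface$vertices[ed[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(matrix(as.character(ed), ncol = 2), directed = FALSE)
  igraph::E(g)$weight <- w
  from <- as.character(loops[[1]][1])
  to <- vapply(loops[[2]], as.character, character(1))
  sp <- igraph::shortest_paths(g, from = from, to = to)$vpath
  lens <- vapply(sp, function(p) {
    ids <- as.integer(igraph::V(g)$name[p])
    sum(sqrt(rowSums((surface$vertices[ids[-1], , drop = FALSE] -
                      surface$vertices[ids[-length(ids)], , drop = FALSE])^2)))
  }, numeric(1))
  p <- sp[[which.min(lens)]]
  as.integer(igraph::V(g)$name[p])
}

# Globally classify the faces incident to the cut path into its two sides.
# Faces incident to a cut vertex are linked when they share a mesh edge that
# contains a cut vertex but is not itself a path edge; the two resulting
# components are the left and right banks of the cut. Returns a logical
# vector over all faces, TRUE on the bank that sees the cut at +2*pi.
cut_sides <- function(surface, cut) {
  f <- surface$faces
  oncut <- matrix(f %in% cut, nrow(f), 3)
  inc <- which(rowSums(oncut) > 0)
  path_edges <- paste(pmin(cut[-length(cut)], cut[-1]),
                      pmax(cut[-length(cut)], cut[-1]))
  ed <- face_edges(f[inc, , drop = FALSE])
  fid <- rep(seq_along(inc), 3)
  has_cut_vertex <- (ed[, 1] %in% cut) | (ed[, 2] %in% cut)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ok <- has_cut_vertex & !(key %in% path_edges)
  # connect faces sharing an eligible edge
  sp <- split(fid[ok], key[ok])
  pairs <- do.call(rbind, lapply(sp[lengths(sp) == 2], function(x) sort(x)))
  gg <- igraph::make_empty_graph(n = length(inc), directed = FALSE)
  if (!is.null(pairs)) gg <- igraph::add_edges(gg, t(pairs))
  comp <- igraph::components(gg)$membership
  if (max(comp) != 2) {
    stop("cut path does not split its incident faces into two banks; ",
         "mesh may be non-manifold near the cut")
  }
  side2 <- rep(FALSE, nrow(f))
  side2[inc[comp == 2]] <- TRUE
  side2
}

# Right-hand side folding the 2*pi period across the cut into the Laplace
# system, assembled per face from cotangent stiffness contributions: in
# side-2 faces every cut vertex is read at phi + 2*pi.
cut_jump_rhs <- function(surface, W, cut, side2) {
  v <- surface$vertices
  f <- surface$faces
  n <- nrow(v)
  rhs <- numeric(n)
  sel <- which(side2 & matrix(f %in% cut, nrow(f), 3) |> rowSums() > 0)
  cotw <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(u * w)
    cr2 <- rowSums(u^2) * rowSums(w^2) - dt^2
    dt / pmax(sqrt(pmax(cr2, 0)), .Machine$double.eps)
  }
  fs <- f[sel, , drop = FALSE]
  # per-face edge weights: edge (1,2) weighted by cot at 3, etc., halved
  w12 <- cotw(fs[, 3], fs[, 1], fs[, 2]) / 2
  w23 <- cotw(fs[, 1], fs[, 2], fs[, 3]) / 2
  w31 <- cotw(fs[, 2], fs[, 3], fs[, 1]) / 2
  off <- matrix(2 * pi * (fs %in% cut), nrow(fs), 3)
  idx <- c(fs[, 1], fs[, 2], fs[, 2], fs[, 3], fs[, 3], fs[, 1])
  val <- c(-w12 * (off[, 1] - off[, 2]),  w12 * (off[, 1] - off[, 2]),
           -w23 * (off[, 2] - off[, 3]),  w23 * (off[, 2] - off[, 3]),
           -w31 * (off[, 3] - off[, 1]),  w31 * (off[, 3] - off[, 1]))
  acc <- tapply(val, idx, sum)
  rhs[as.integer(names(acc))] <- as.numeric(acc)
  list(rhs = rhs)
}

solve_fixed_one <- function(L, rhs, anchor, n) {
  free <- setdiff(seq_len(n), anchor)
  x <- numeric(n)
  A <- L[free, free, drop = FALSE]
  b <- rhs[free]
  x[free] <- as.numeric(Matrix::solve(A, b))
  x
}

#' Per-face tangent frames from the chart
#'
#' For each face, the 3D directions of increasing `s` and `phi` are computed
#' from the affine map of the triangle's chart coordinates and
#' orthonormalized by Gram-Schmidt with the `s` direction first. Frames are
#' made right-handed with the inward face normal. Faces straddling the
#' `phi` seam use locally unwrapped copies.
#'
#' @param surface a [tube_surface()] with chart.
#' @return A tibble with one row per face: `face`, `s_hat_*`, `phi_hat_*`
#'   (components of the two unit vectors), `normal_*`.
#' @export
tangent_directions <- function(surface) {
  if (is.null(surface$chart)) stop("surface has no chart")
  f <- surface$faces
  fg <- face_geometry(surface)
  uv <- face_chart_uv(surface)
  e1c <- uv$u2 - uv$u1
  e2c <- uv$u3 - uv$u1
  det <- e1c[, 1] * e2c[, 2] - e1c[, 2] * e2c[, 1]
  if (any(abs(det) < 1e-14)) {
    stop("chart-degenerate face(s): ",
         paste(utils::head(which(abs(det) < 1e-14), 5), collapse = ", "))
  }
  E1 <- fg$p2 - fg$p1
  E2 <- fg$p3 - fg$p1
  # columns of the inverse chart-edge matrix
  inv11 <- e2c[, 2] / det; inv12 <- -e2c[, 1] / det
  inv21 <- -e1c[, 2] / det; inv22 <- e1c[, 1] / det
  dX_ds <- E1 * inv11 + E2 * inv21
  dX_dphi <- E1 * inv12 + E2 * inv22
  s_hat <- dX_ds / sqrt(rowSums(dX_ds^2))
  proj <- rowSums(dX_dphi * s_hat)
  phi_raw <- dX_dphi - s_hat * proj
  phi_hat <- phi_raw / sqrt(rowSums(phi_raw^2))
  # enforce right-handedness with the inward normal
  cr <- cbind(s_hat[, 2] * phi_hat[, 3] - s_hat[, 3] * phi_hat[, 2],
              s_hat[, 3] * phi_hat[, 1] - s_hat[, 1] * phi_hat[, 3],
              s_hat[, 1] * phi_hat[, 2] - s_hat[, 2] * phi_hat[, 1])
  flip <- rowSums(cr * fg$normal) < 0
  phi_hat[flip, ] <- -phi_hat[flip, , drop = FALSE]
  tibble::tibble(
    face = seq_len(nrow(f)),
    s_hat_x = s_hat[, 1], s_hat_y = s_hat[, 2], s_hat_z = s_hat[, 3],
    phi_hat_x = phi_hat[, 1], phi_hat_y = phi_hat[, 2], phi_hat_z = phi_hat[, 3],
    normal_x = fg$normal[, 1], normal_y = fg$normal[, 2], normal_z = fg$normal[, 3]
  )
}

# Chart coordinates of the three corners of each face, with phi unwrapped
# within the face (seam-aware): if the three phi values span more than pi,
# small values are shifted up by 2*pi.
face_chart_uv <- function(surface) {
  ch <- surface$chart
  f <- surface$faces
  s1 <- ch$s[f[, 1]]; s2 <- ch$s[f[, 2]]; s3 <- ch$s[f[, 3]]
  p1 <- ch$phi[f[, 1]]; p2 <- ch$phi[f[, 2]]; p3 <- ch$phi[f[, 3]]
  pm <- cbind(p1, p2, p3)
  spread <- apply(pm, 1, function(r) diff(range(r)))
  wrap <- spread > pi
  if (any(wrap)) {
    pmw <- pm[wrap, , drop = FALSE]
    pmw[pmw < pi] <- pmw[pmw < pi] + 2 * pi
    pm[wrap, ] <- pmw
  }
  list(u1 = cbind(s1, pm[, 1]), u2 = cbind(s2, pm[, 2]), u3 = cbind(s3, pm[, 3]))
}
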