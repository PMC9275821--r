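# Synthetic constricting-tube sequences with the exact area-preserving
# Lagrangian flow, plus closed-form kinematic fields for oracle testing.
#
# The tube is a surface of revolution with radius profile
#   r(z, t) = R0 - sum_j d_j(t) * exp(-(z - c_j)^2 / (2 w_j^2)),
# localized Gaussian constrictions deepening in time. Marker (material)
# axial positions z(u, t) are chosen so that the area element
# a(z) = r * sqrt(1 + r_z^2) integrates to the same cumulative area for
# every marker at every time: the flow is exactly area preserving, the
# anterior end (z = 0) is anchored, and the tube extends at the posterior
# end — convergent extension via constriction in its cleanest form.

#' Specification of a synthetic constricting tube
#'
#' @param R0 rest radius (micrometres).
#' @param L0 rest length (micrometres).
#' @param constrictions data frame with columns `center` (position along the
#'   axis, micrometres), `depth` (final depth, micrometres, `< R0`) and
#'   `width` (Gaussian sigma, micrometres); up to three rows.
#' @param n_s,n_phi mesh resolution: rings along the axis / vertices per ring
#'   (both `>= 16`).
#' @param dt timestep in minutes.
#' @param n_t number of timepoints.
#' @param ramp function mapping normalized time in `[0, 1]` to the fraction
#'   of the final depth; defaults to a linear ramp. The waveform of real
#'   constrictions is not prescribed by the data, so it is configuration.
#' @param seed integer seed (kept for provenance; the flow is deterministic).
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(R0 = 30, L0 = 200,
                      constrictions = data.frame(center = L0 / 2,
                                                 depth = 0.6 * R0,
                                                 width = 15),
                      n_s = 128, n_phi = 64, dt = 1, n_t = 30,
                      ramp = function(x) x, seed = 1L) {
  constrictions <- as.data.frame(constrictions)
  stopifnot(all(c("center", "depth", "width") %in% names(constrictions)),
            nrow(constrictions) <= 3,
            n_s >= 16, n_phi >= 16, dt > 0, n_t >= 1, R0 > 0, L0 > 0)
  if (any(constrictions$depth >= R0)) stop("constriction depth must stay below R0 (neck never closes)")
  if (any(constrictions$width <= 0)) stop("constriction width must be positive")
  structure(list(R0 = R0, L0 = L0, constrictions = constrictions,
                 n_s = as.integer(n_s), n_phi = as.integer(n_phi),
                 dt = dt, n_t = as.integer(n_t), ramp = ramp,
                 seed = as.integer(seed)),
            class = "tube_spec")
}

# radius profile and partial derivatives at axial positions z, with
# per-constriction depths d (vector) and depth rates ddot
tube_profile <- function(z, spec, d, ddot = NULL) {
  r <- rep(spec$R0, length(z))
  rz <- rzz <- rt <- rzt <- numeric(length(z))
  for (j in seq_len(nrow(spec$constrictions))) {
    cj <- spec$constrictions$center[j]
    wj <- spec$constrictions$width[j]
    g <- exp(-(z - cj)^2 / (2 * wj^2))
    gz <- -(z - cj) / wj^2 * g
    gzz <- ((z - cj)^2 / wj^4 - 1 / wj^2) * g
    r <- r - d[j] * g
    rz <- rz - d[j] * gz
    rzz <- rzz - d[j] * gzz
    if (!is.null(ddot)) {
      rt <- rt - ddot[j] * g
      rzt <- rzt - ddot[j] * gz
    }
  }
  list(r = r, rz = rz, rzz = rzz, rt = rt, rzt = rzt)
}

# cumulative trapezoid
cumtrapz1 <- function(x, y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))

# Areas of the two triangles of one band quad: rings at (z1, r1) and
# (z2, r2), ring 2 rotated by a relative twist tau. All quads of a band are
# congruent by the n_phi-fold symmetry.
band_tri_areas <- function(z1, z2, r1, r2, tau, n_phi) {
  dphi <- 2 * pi / n_phi
  a <- c(r1, 0, z1)
  b <- c(r1 * cos(dphi), r1 * sin(dphi), z1)
  cc <- c(r2 * cos(tau), r2 * sin(tau), z2)
  d <- c(r2 * cos(dphi + tau), r2 * sin(dphi + tau), z2)
  tri <- function(p, q, r) {
    u <- q - p; v <- r - p
    cx <- u[2] * v[3] - u[3] * v[2]
    cy <- u[3] * v[1] - u[1] * v[3]
    cz <- u[1] * v[2] - u[2] * v[1]
    0.5 * sqrt(cx * cx + cy * cy + cz * cz)
  }
  c(tri(a, d, b), tri(a, cc, d))  # faces (a,d,b) and (a,c,d)
}

# Sequentially relocate markers so every quadrilateral band cell (pair of
# triangles) of the mesh keeps its initial discrete area exactly; anchored
# at z = 0 and solved ring by ring with uniroot. The *individual* triangle
# areas of a band cell are proportional to the two ring circumferences, a
# split fixed by the radius profile, so they carry an O(ds) sampling
# asymmetry that no Lagrangian marker placement can remove; the conserved
# discrete quantity is the cell (quad) area, which tracks the continuum
# area element.
refine_marker_positions <- function(z0, spec, d) {
  n_s <- spec$n_s
  n_phi <- spec$n_phi
  du <- spec$L0 / (n_s - 1)
  target <- sum(band_tri_areas(0, du, spec$R0, spec$R0, 0, n_phi))
  rad <- function(z) tube_profile(z, spec, d)$r
  z <- numeric(n_s)
  for (i in seq_len(n_s - 1)) {
    r1 <- rad(z[i])
    f <- function(zz) sum(band_tri_areas(z[i], zz, r1, rad(zz), 0, n_phi)) - target
    sol <- tryCatch(
      stats::uniroot(f, c(z[i] + 1e-9, z[i] + 6 * du), tol = 1e-13),
      error = function(e) NULL)
    if (is.null(sol)) {
      stop(sprintf("discrete area inversion failed between rings %d and %d", i, i + 1))
    }
    z[i + 1] <- sol$root
  }
  list(z = z, twist = numeric(n_s))
}

#' Generate an area-preserving constricting-tube sequence
#'
#' Constructs the unique axisymmetric Lagrangian flow under which every
#' material patch of the tube keeps its area exactly while Gaussian
#' constrictions deepen: marker axial positions are found by inverting the
#' cumulative area integral by quadrature. Returns the meshed sequence
#' together with analytic per-marker kinematic fields (`H`, `vn`,
#' `div = 2 H vn`, velocity) evaluated from the parametric form.
#'
#' @param spec a [tube_spec()].
#' @param n_quad quadrature grid size for the area integral.
#' @return A [surface_sequence()] with attributes `analytic` (tibble of
#'   per-ring fields: `t`, `u`, `z`, `r`, `H`, `vn`, `div`, `vz`, `vr`) and
#'   `spec`.
#' @export
make_constricting_tube <- function(spec, n_quad = 4096) {
  stopifnot(inherits(spec, "tube_spec"))
  times <- seq(0, by = spec$dt, length.out = spec$n_t)
  tnorm <- if (spec$n_t > 1) (times - times[1]) / (times[spec$n_t] - times[1]) else 0
  depth_at <- function(k) spec$constrictions$depth * spec$ramp(tnorm[k])
  # depth rate by differentiating the ramp numerically (exact for linear)
  eps <- 1e-6
  depth_rate <- function(k) {
    x <- tnorm[k]
    h <- eps
    dr <- (spec$ramp(min(x + h, 1)) - spec$ramp(max(x - h, 0))) /
      (min(x + h, 1) - max(x - h, 0))
    spec$constrictions$depth * dr / (times[spec$n_t] - times[1] + (spec$n_t == 1))
  }
  zq <- seq(0, 2 * spec$L0, length.out = n_quad)
  u <- seq(0, spec$L0, length.out = spec$n_s)
  # target cumulative areas fixed at t = 0 (d = 0: uniform cylinder)
  A0 <- spec$R0 * u
  surfaces <- vector("list", spec$n_t)
  analytic <- vector("list", spec$n_t)
  phi <- seq(0, 2 * pi, length.out = spec$n_phi + 1)[1:spec$n_phi]
  faces <- structured_tube_faces(spec$n_s, spec$n_phi)
  chart <- tibble::tibble(vertex_id = seq_len(spec$n_s * spec$n_phi),
                          s = rep(u, each = spec$n_phi),
                          phi = rep(phi, spec$n_s))
  for (k in seq_len(spec$n_t)) {
    d <- depth_at(k)
    ddot <- depth_rate(k)
    pq <- tube_profile(zq, spec, d, ddot)
    if (min(pq$r) <= 0.05 * spec$R0) {
      stop(sprintf("constriction too deep at timestep %d: neck radius %.3g",
                   k, min(pq$r)))
    }
    aq <- pq$r * sqrt(1 + pq$rz^2)
    Aq <- cumtrapz1(zq, aq)
    if (any(diff(Aq) <= 0) || max(Aq) < max(A0)) {
      stop(sprintf("area inversion failed at timestep %d (neck too deep/narrow)", k))
    }
    z <- stats::approx(Aq, zq, xout = A0, ties = "ordered")$y
    # refine marker positions so the *discrete* mesh triangle areas are
    # conserved exactly (the quadrature solution preserves the continuum
    # area element; at finite resolution triangle areas would still drift)
    ref <- refine_marker_positions(z, spec, d)
    z <- ref$z
    twist <- ref$twist
    pm <- tube_profile(z, spec, d, ddot)
    # marker axial velocity from conservation: dA/dt + a * zdot = 0
    atq <- pq$rt * sqrt(1 + pq$rz^2) + pq$r * pq$rz * pq$rzt / sqrt(1 + pq$rz^2)
    Atq <- cumtrapz1(zq, atq)
    At <- stats::approx(zq, Atq, xout = z, ties = "ordered")$y
    am <- pm$r * sqrt(1 + pm$rz^2)
    vz <- -At / am
    vr <- pm$rt + pm$rz * vz
    sq <- sqrt(1 + pm$rz^2)
    H <- 0.5 * (1 / (pm$r * sq) - pm$rzz / sq^3)
    vn <- -pm$rt / sq
    analytic[[k]] <- tibble::tibble(
      t = times[k], u = u, z = z, r = pm$r,
      H = H, vn = vn, div = 2 * H * vn, vz = vz, vr = vr
    )
    ang <- rep(phi, spec$n_s) + rep(twist, each = spec$n_phi)
    verts <- cbind(
      rep(pm$r, each = spec$n_phi) * cos(ang),
      rep(pm$r, each = spec$n_phi) * sin(ang),
      rep(z, each = spec$n_phi)
    )
    surfaces[[k]] <- tube_surface(verts, faces, chart)
  }
  seq <- surface_sequence(surfaces, times)
  attr(seq, "analytic") <- dplyr::bind_rows(analytic)
  attr(seq, "spec") <- spec
  attr(seq, "parametric") <- "constricting_tube"
  seq
}

#' Sphere sequence with purely normal motion
#'
#' An analytic oracle: a sphere whose radius follows `R_of_t`, moving purely
#' normally, so the covariant divergence of the tangential velocity is zero
#' and the residual of the incompressibility relation equals the area
#' growth rate `2 * Rdot / R`.
#'
#' @param R_of_t function of time (minutes) returning the radius.
#' @param n_t number of timepoints.
#' @param dt timestep (minutes).
#' @param subdiv icosphere subdivision level.
#' @return A [surface_sequence()] with attribute `analytic`: tibble of
#'   `t`, `R`, `Rdot`, `H`, `vn`, `div`, `residual`.
#' @export
make_sphere_sequence <- function(R_of_t, n_t, dt = 1, subdiv = 3) {
  times <- seq(0, by = dt, length.out = n_t)
  R <- vapply(times, R_of_t, numeric(1))
  if (any(R <= 0)) stop("R(t) must be positive")
  base <- mesh_icosphere(1, subdiv)
  surfaces <- lapply(R, function(rr) tube_surface(base$vertices * rr, base$faces))
  h <- 1e-5
  Rdot <- vapply(times, function(tt) (R_of_t(tt + h) - R_of_t(max(tt - h, 0))) /
                   (tt + h - max(tt - h, 0)), numeric(1))
  analytic <- tibble::tibble(
    t = times, R = R, Rdot = Rdot,
    H = 1 / R, vn = -Rdot, div = 0, residual = 2 * Rdot / R
  )
  seq <- surface_sequence(surfaces, times)
  attr(seq, "analytic") <- analytic
  attr(seq, "parametric") <- "sphere"
  seq
}
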