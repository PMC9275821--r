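# Material-frame shear via the Beltrami coefficient: anisotropy of the map
# from an isotropy-normalized reference chart (fixed at the onset of
# constriction) to the deforming surface.

#' Material chart with isotropy-normalized reference metric
#'
#' Fixes material coordinates `(zeta, phi)` at a reference timepoint
#' (by default the first, taken as the onset of the first constriction):
#' `zeta(s)` integrates `sqrt(g_ss / g_phiphi)` so that the reference
#' pullback is conformal for near-axisymmetric shapes, and the per-face
#' reference metric `g0` is stored so that subsequent deformation is
#' measured relative to it (making the reference exactly isotropic
#' face-by-face). The residual anisotropy of the `zeta` chart itself is
#' reported in attribute `ref_mu_max` and should be small (`< 0.05`).
#'
#' @param seq a [surface_sequence()] with charts.
#' @param t0_index reference timepoint index (default 1).
#' @param n_s_bins number of s-bins used to build `zeta(s)`.
#' @return object of class `material_chart`: list with `chart`
#'   (tibble `vertex_id`, `zeta`, `phi`), `g0` (per-face reference metric
#'   tibble), `faces`, `t0`, `s` (material s labels).
#' @export
material_chart <- function(seq, t0_index = 1, n_s_bins = 64) {
  surf <- seq$surfaces[[t0_index]]
  if (is.null(surf$chart)) stop("reference surface needs a chart")
  g_sp <- induced_metric_chart(surf)
  ch <- surf$chart
  fa <- face_areas(surf)
  s_face <- (ch$s[surf$faces[, 1]] + ch$s[surf$faces[, 2]] + ch$s[surf$faces[, 3]]) / 3
  rng <- range(ch$s)
  # never use more bins than the mesh can populate
  n_s_bins <- min(n_s_bins, max(4L, floor(length(unique(round(s_face, 9))) / 2)))
  br <- seq(rng[1], rng[2], length.out = n_s_bins + 1)
  bin <- pmin(findInterval(s_face, br, rightmost.closed = TRUE), n_s_bins)
  ratio <- sqrt(g_sp$g11 / g_sp$g22)      # d zeta / d s per face
  mids <- (br[-1] + br[-(n_s_bins + 1)]) / 2
  fbin <- vapply(seq_len(n_s_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NA_real_)
    sum(ratio[sel] * fa[sel]) / sum(fa[sel])
  }, numeric(1))
  if (anyNA(fbin)) stop("empty s-bin while building the material chart")
  # integrate d zeta/d s over bin midpoints, extended linearly to the chart
  # ends so end-band faces are not flattened
  grid_s <- c(rng[1], mids, rng[2])
  grid_f <- c(fbin[1], fbin, fbin[n_s_bins])
  zeta_grid <- cumtrapz1(grid_s, grid_f)
  zeta_v <- stats::approx(grid_s, zeta_grid, xout = ch$s, ties = "ordered")$y
  mat <- list(
    chart = tibble::tibble(vertex_id = ch$vertex_id, zeta = zeta_v, phi = ch$phi),
    faces = surf$faces,
    t0 = seq$time[t0_index],
    s = ch$s
  )
  class(mat) <- "material_chart"
  g0 <- induced_metric(surf, mat, relative = FALSE)
  mat$g0 <- g0
  mu0 <- beltrami(g0)
  attr(mat, "ref_mu_max") <- max(Mod(mu0))
  mat
}

#' @export
print.material_chart <- function(x, ...) {
  cat(sprintf("<material_chart> t0 = %g min, %d vertices, residual |mu(t0)| <= %.4f\n",
              x$t0, nrow(x$chart), attr(x, "ref_mu_max")))
  invisible(x)
}

# induced metric of a surface relative to its own (s, phi) chart
induced_metric_chart <- function(surface) {
  uv <- face_chart_uv(surface)
  metric_from_uv(surface, uv$u1, uv$u2, uv$u3)
}

metric_from_uv <- function(surface, u1, u2, u3) {
  fg <- face_geometry(surface)
  e1c <- u2 - u1
  e2c <- u3 - u1
  det <- e1c[, 1] * e2c[, 2] - e1c[, 2] * e2c[, 1]
  if (any(abs(det) < 1e-14)) {
    stop("degenerate triangle in chart at face(s): ",
         paste(utils::head(which(abs(det) < 1e-14), 5), collapse = ", "))
  }
  E1 <- fg$p2 - fg$p1
  E2 <- fg$p3 - fg$p1
  inv11 <- e2c[, 2] / det; inv12 <- -e2c[, 1] / det
  inv21 <- -e1c[, 2] / det; inv22 <- e1c[, 1] / det
  dX1 <- E1 * inv11 + E2 * inv21   # dX / d(coord 1)
  dX2 <- E1 * inv12 + E2 * inv22
  tibble::tibble(
    face = seq_len(nrow(surface$faces)),
    g11 = rowSums(dX1 * dX1),
    g12 = rowSums(dX1 * dX2),
    g22 = rowSums(dX2 * dX2)
  )
}

#' Induced metric relative to the material chart
#'
#' Per-triangle metric `g'_ij = dX_i . dX_j` of the affine map from
#' material coordinates `(zeta, phi)` to the 3D surface at a later time,
#' using the Lagrangian vertex correspondence. With `relative = TRUE`
#' (default) the metric is normalized by the per-face reference metric
#' `g0` (Cholesky transform), so that `g' = identity` at the reference
#' time.
#'
#' @param surface_t the [tube_surface()] at time t (same vertex ids).
#' @param mchart a [material_chart()].
#' @param relative normalize by the reference metric?
#' @return tibble with `face`, `g11`, `g12`, `g22`.
#' @export
induced_metric <- function(surface_t, mchart, relative = TRUE) {
  ch <- mchart$chart
  f <- mchart$faces
  if (nrow(surface_t$vertices) != nrow(ch)) stop("vertex correspondence mismatch")
  phiv <- ch$phi
  pm <- cbind(phiv[f[, 1]], phiv[f[, 2]], phiv[f[, 3]])
  spread <- apply(pm, 1, function(r) diff(range(r)))
  wrap <- spread > pi
  if (any(wrap)) {
    pmw <- pm[wrap, , drop = FALSE]
    pmw[pmw < pi] <- pmw[pmw < pi] + 2 * pi
    pm[wrap, ] <- pmw
  }
  z <- ch$zeta
  u1 <- cbind(z[f[, 1]], pm[, 1])
  u2 <- cbind(z[f[, 2]], pm[, 2])
  u3 <- cbind(z[f[, 3]], pm[, 3])
  surf <- surface_t
  surf$faces <- f
  g <- metric_from_uv(surf, u1, u2, u3)
  if (relative) {
    g0 <- mchart$g0
    g <- normalize_metric(g, g0)
  }
  g
}

# g_tilde = M^T g M with M = chol(g0)^{-1}, so g0 maps to the identity.
normalize_metric <- function(g, g0) {
  # chol of 2x2 SPD: [[a, b], [0, c]] upper with a = sqrt(g11),
  # b = g12 / a, c = sqrt(g22 - b^2)
  a <- sqrt(g0$g11)
  b <- g0$g12 / a
  c <- sqrt(pmax(g0$g22 - b^2, .Machine$double.eps))
  # M = inv([[a, b],[0, c]]) = [[1/a, -b/(a c)], [0, 1/c]]
  m11 <- 1 / a; m12 <- -b / (a * c); m22 <- 1 / c
  h11 <- g$g11 * m11^2
  h12 <- m11 * (g$g11 * m12 + g$g12 * m22)
  h22 <- g$g11 * m12^2 + 2 * g$g12 * m12 * m22 + g$g22 * m22^2
  tibble::tibble(face = g$face, g11 = h11, g12 = h12, g22 = h22)
}

#' Beltrami coefficient of a metric
#'
#' `mu = (g11 - g22 + 2i g12) / (g11 + g22 + 2 sqrt(det g))`, the bounded
#' complex measure of anisotropy of the material map: `|mu| < 1` for every
#' positive-definite metric, `mu = 0` iff the metric is conformal, and
#' `arg(mu) / 2` is the orientation of the stretch axis relative to the
#' first coordinate direction.
#'
#' @param g tibble with `g11`, `g12`, `g22` (or a numeric length-3 vector
#'   `c(g11, g12, g22)`).
#' @return complex vector of Beltrami coefficients.
#' @export
beltrami <- function(g) {
  if (is.numeric(g) && length(g) == 3) {
    g <- tibble::tibble(g11 = g[1], g12 = g[2], g22 = g[3])
  }
  det <- g$g11 * g$g22 - g$g12^2
  if (any(det <= 0) || any(g$g11 <= 0)) {
    stop("metric is not positive definite at face(s): ",
         paste(utils::head(which(det <= 0 | g$g11 <= 0), 5), collapse = ", "))
  }
  denom <- g$g11 + g$g22 + 2 * sqrt(det)
  complex(real = (g$g11 - g$g22) / denom, imaginary = 2 * g$g12 / denom)
}

#' Anisotropy ratio from the Beltrami coefficient
#'
#' `K = (1 + |mu|) / (1 - |mu|)`: the axis ratio of the ellipse into which
#' the material map takes an infinitesimal circle. `K = 1` iff the map is
#' isotropic; `K` equals the singular-value ratio of the per-triangle
#' linear map.
#'
#' @param mu complex Beltrami coefficient(s).
#' @return numeric `K >= 1`.
#' @export
anisotropy_ratio <- function(mu) {
  m <- Mod(mu)
  if (any(m >= 1)) stop("|mu| must be < 1")
  (1 + m) / (1 - m)
}

#' Shear kymograph
#'
#' Circumferentially averaged Beltrami coefficient per material s-bin and
#' timepoint. Averaging is complex (area-weighted) by default, so opposite
#' orientations cancel; `average = "magnitude"` averages `|mu|` instead.
#'
#' @param seq a [surface_sequence()].
#' @param mchart a [material_chart()] built from `seq`.
#' @param n_s_bins number of material AP bins.
#' @param average `"complex"` or `"magnitude"`.
#' @return tibble of class `shear_kymograph`: `t`, `s_bin`, `s_mid`,
#'   `re_mu`, `im_mu`, `mod_mu`, `K`.
#' @export
shear_kymograph <- function(seq, mchart, n_s_bins = 20, average = c("complex", "magnitude")) {
  average <- match.arg(average)
  f <- mchart$faces
  s_face <- (mchart$s[f[, 1]] + mchart$s[f[, 2]] + mchart$s[f[, 3]]) / 3
  rng <- range(mchart$s)
  br <- seq(rng[1], rng[2], length.out = n_s_bins + 1)
  bin <- pmin(findInterval(s_face, br, rightmost.closed = TRUE), n_s_bins)
  if (length(unique(bin)) < n_s_bins) stop("empty s-bin in kymograph")
  mids <- (br[-1] + br[-(n_s_bins + 1)]) / 2
  rows <- purrr::map(seq_along(seq$time), function(k) {
    surf <- seq$surfaces[[k]]
    g <- induced_metric(surf, mchart)
    mu <- beltrami(g)
    fa <- face_areas(surf)
    agg <- vapply(seq_len(n_s_bins), function(b) {
      sel <- bin == b
      w <- fa[sel] / sum(fa[sel])
      if (average == "complex") {
        m <- sum(mu[sel] * w)
        c(Re(m), Im(m), Mod(m))
      } else {
        mm <- sum(Mod(mu[sel]) * w)
        c(NA_real_, NA_real_, mm)
      }
    }, numeric(3))
    tibble::tibble(
      t = seq$time[k], s_bin = seq_len(n_s_bins), s_mid = mids,
      re_mu = agg[1, ], im_mu = agg[2, ], mod_mu = agg[3, ],
      K = (1 + agg[3, ]) / (1 - agg[3, ])
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shear_kymograph", class(out))
  out
}
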