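# Velocity decomposition on evolving surfaces and the incompressibility
# test: does the out-of-plane deformation 2*H*vn account for the covariant
# in-plane divergence of the tangential tissue velocity?

#' Lagrangian velocity field
#'
#' Velocities are forward finite differences of vertex positions between
#' consecutive timepoints (one-sided at the last timepoint), using the
#' Lagrangian vertex correspondence of the sequence. The decomposition into
#' tangential and normal parts is evaluated on the midpoint surface
#' `(X(t) + X(t+dt)) / 2`, which centers the discrete fields in time.
#' `vn` is positive for inward motion (toward the lumen).
#'
#' @param seq a [surface_sequence()].
#' @param t_index timepoint index (velocity from `t_index` to `t_index + 1`).
#' @return A tibble with one row per vertex: `vertex_id`, `vx,vy,vz`,
#'   `vn`, `vpx,vpy,vpz` (tangential part); attribute `midpoint` holds the
#'   midpoint [tube_surface()] on which normals were taken.
#' @export
lagrangian_velocity <- function(seq, t_index) {
  stopifnot(inherits(seq, "surface_sequence"))
  n_t <- length(seq$time)
  if (t_index < 1 || t_index > n_t) stop("missing timepoint: ", t_index)
  i0 <- if (t_index == n_t) t_index - 1L else t_index
  if (i0 < 1) stop("velocity needs at least two timepoints")
  dt <- seq$time[i0 + 1] - seq$time[i0]
  X0 <- seq$surfaces[[i0]]$vertices
  X1 <- seq$surfaces[[i0 + 1]]$vertices
  v <- (X1 - X0) / dt
  mid <- seq$surfaces[[i0]]
  mid$vertices <- (X0 + X1) / 2
  nrm <- vertex_normals(mid)
  vn <- rowSums(v * nrm)
  vp <- v - nrm * vn
  out <- tibble::tibble(
    vertex_id = seq_len(nrow(v)),
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    vn = vn,
    vpx = vp[, 1], vpy = vp[, 2], vpz = vp[, 3]
  )
  attr(out, "midpoint") <- mid
  attr(out, "dt") <- dt
  out
}

#' Covariant divergence of a tangential vector field
#'
#' Discrete-exterior-calculus divergence: the vector field is sampled as a
#' 1-form on edges (midpoint rule) and the codifferential is taken with
#' cotangent (dual-edge / primal-edge) weights, divided by the vertex area.
#' By construction the discrete divergence theorem holds exactly on any
#' vertex subset: the area-weighted sum of the divergence over the subset
#' equals the sum of weighted 1-form values on its cut edges.
#'
#' @param surface a [tube_surface()].
#' @param vfield numeric `n x 3` matrix of per-vertex vectors (tangential;
#'   a non-tangential component beyond `tol` is an error).
#' @param tol maximum allowed normal component relative to the field scale.
#' @return numeric vector of per-vertex divergence (1/min when the field is
#'   a velocity in micrometres/min).
#' @export
covariant_divergence <- function(surface, vfield, tol = 1e-6) {
  vfield <- as.matrix(vfield)
  stopifnot(nrow(vfield) == nrow(surface$vertices))
  nrm <- vertex_normals(surface)
  scale <- max(sqrt(rowSums(vfield^2)), .Machine$double.eps)
  # boundary vertex normals tilt into the missing one-ring; judge
  # tangentiality on interior vertices
  iv <- setdiff(seq_len(nrow(vfield)), boundary_vertices(surface))
  worst <- max(abs(rowSums(vfield * nrm)[iv]))
  if (worst > tol * scale) {
    stop(sprintf("input field is not tangential: max normal component %.3g (scale %.3g)",
                 worst, scale))
  }
  lap <- cotan_laplacian(surface)
  A <- vertex_areas(surface)
  div_from_oneform(surface, vfield, lap$W, A)
}

# shared kernel: DEC codifferential of the flattened field
div_from_oneform <- function(surface, vfield, W, A) {
  n <- nrow(surface$vertices)
  Wt <- methods::as(methods::as(W, "generalMatrix"), "TsparseMatrix")
  i <- Wt@i + 1L
  j <- Wt@j + 1L
  w <- Wt@x
  keep <- i < j
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  e <- surface$vertices[j, , drop = FALSE] - surface$vertices[i, , drop = FALSE]
  vm <- (vfield[i, , drop = FALSE] + vfield[j, , drop = FALSE]) / 2
  alpha <- rowSums(vm * e)               # 1-form on edge i -> j
  contrib <- w * alpha
  div <- numeric(n)
  acc_i <- tapply(contrib, i, sum)
  div[as.integer(names(acc_i))] <- as.numeric(acc_i)
  acc_j <- tapply(-contrib, j, sum)
  idx <- as.integer(names(acc_j))
  div[idx] <- div[idx] + as.numeric(acc_j)
  div / A
}

#' Patch-averaged incompressibility fields
#'
#' Computes, for the step from timepoint `t_index` to `t_index + 1`,
#' area-weighted patch averages of the mean curvature `H`, the normal
#' velocity `vn`, the out-of-plane deformation `oop = 2*H*vn`, the
#' covariant divergence `div` of the tangential velocity, and the residual
#' `div - oop`, on a rectangular grid of bins in the material `(s, phi)`
#' chart. The independently measured local area growth rate
#' `d log A / dt` (from triangle areas at the two timepoints) is included
#' as a cross-check: for smooth flows it matches the residual.
#'
#' @param seq a [surface_sequence()] whose surfaces carry a chart.
#' @param t_index starting timepoint index.
#' @param n_s_bins,n_phi_bins patch grid (default 20 x 16 = 320 patches).
#' @return A tibble of class `kinematic_fields`: one row per patch with
#'   `t`, `s_bin`, `phi_bin`, `s_mid`, `area`, `H`, `vn`, `div`, `oop`,
#'   `residual`, `dlogA_dt`.
#' @export
incompressibility_fields <- function(seq, t_index, n_s_bins = 20, n_phi_bins = 16) {
  surf0 <- seq$surfaces[[t_index]]
  if (is.null(surf0$chart)) stop("sequence surfaces need a chart")
  vel <- lagrangian_velocity(seq, t_index)
  mid <- attr(vel, "midpoint")
  lap <- cotan_laplacian(mid)
  Av <- vertex_areas(mid)
  H <- mean_curvature(mid)
  vp <- cbind(vel$vpx, vel$vpy, vel$vpz)
  div_v <- div_from_oneform(mid, vp, lap$W, Av)
  # replace boundary-vertex values (incomplete stencils) by interior means,
  # mirroring mean_curvature()
  bv <- boundary_vertices(mid)
  if (length(bv) > 0) {
    for (b in bv) {
      nb <- setdiff(which(lap$W[b, ] != 0), bv)
      div_v[b] <- if (length(nb) > 0) mean(div_v[nb]) else NA_real_
    }
  }
  f <- mid$faces
  fa_mid <- face_areas(mid)
  fa0 <- face_areas(seq$surfaces[[t_index]])
  i1 <- min(t_index + 1L, length(seq$time))
  fa1 <- face_areas(seq$surfaces[[i1]])
  dt <- attr(vel, "dt")
  face_mean <- function(x) (x[f[, 1]] + x[f[, 2]] + x[f[, 3]]) / 3
  Hf <- face_mean(H)
  vnf <- face_mean(vel$vn)
  divf <- face_mean(div_v)
  ch <- surf0$chart
  s_face <- face_mean(ch$s)
  # circular mean of phi over the face corners (seam-aware)
  phiv <- ch$phi
  phi_face <- atan2(face_mean(sin(phiv)), face_mean(cos(phiv))) %% (2 * pi)
  s_rng <- range(ch$s)
  s_bin <- pmin(1L + floor((s_face - s_rng[1]) / diff(s_rng) * n_s_bins), n_s_bins)
  phi_bin <- pmin(1L + floor(phi_face / (2 * pi) * n_phi_bins), n_phi_bins)
  df <- tibble::tibble(
    s_bin = s_bin, phi_bin = phi_bin, area = fa_mid,
    H = Hf, vn = vnf, div = divf,
    dlogA = log(fa1 / fa0) / dt, s_face = s_face
  )
  out <- df |>
    dplyr::group_by(s_bin, phi_bin) |>
    dplyr::summarise(
      s_mid = sum(s_face * area) / sum(area),
      oop = sum(2 * H * vn * area) / sum(area),   # before H/vn are overwritten
      H = sum(H * area) / sum(area),
      vn = sum(vn * area) / sum(area),
      div = sum(div * area) / sum(area),
      dlogA_dt = sum(dlogA * area) / sum(area),
      area = sum(area),
      .groups = "drop"
    )
  if (nrow(out) < n_s_bins * n_phi_bins) stop("empty patch(es) in the (s, phi) grid")
  out$residual <- out$div - out$oop
  out$t <- seq$time[t_index]
  out <- dplyr::select(out, t, s_bin, phi_bin, s_mid, area, H, vn, div, oop,
                       residual, dlogA_dt)
  class(out) <- c("kinematic_fields", class(out))
  out
}

#' Incompressibility fields pooled over a whole sequence
#'
#' @param seq a [surface_sequence()].
#' @param n_s_bins,n_phi_bins patch grid.
#' @return row-bound [incompressibility_fields()] tibbles for every step.
#' @export
incompressibility_fields_sequence <- function(seq, n_s_bins = 20, n_phi_bins = 16) {
  out <- purrr::map(seq_len(length(seq$time) - 1),
                    ~ incompressibility_fields(seq, .x, n_s_bins, n_phi_bins))
  out <- dplyr::bind_rows(out)
  class(out) <- c("kinematic_fields", class(out))
  out
}

#' Correlation between out-of-plane deformation and in-plane divergence
#'
#' Pools all (patch, timepoint) samples and reports the Pearson correlation
#' and the regression slope of `oop = 2*H*vn` against `div`. Area weighting
#' (the default) gives every piece of tissue equal say; the unweighted
#' variant is available for comparison. The correlation is invariant to
#' uniform rescaling of either field.
#'
#' @param fields a `kinematic_fields` tibble.
#' @param weighted use patch areas as weights (default TRUE).
#' @return object of class `incompressibility_fit` with elements `r`,
#'   `slope`, `intercept`, `n`, `weighted`, `residual_rms`.
#' @export
incompressibility_correlation <- function(fields, weighted = TRUE) {
  x <- fields$div
  y <- fields$oop
  w <- if (weighted) fields$area else rep(1, nrow(fields))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance field")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cov <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  r <- cov / sqrt(vx * vy)
  slope <- cov / vx
  structure(
    list(r = r, slope = slope, intercept = my - slope * mx,
         n = nrow(fields), weighted = weighted,
         residual_rms = sqrt(sum(w * (fields$residual)^2))),
    class = "incompressibility_fit"
  )
}

#' @export
print.incompressibility_fit <- function(x, ...) {
  cat(sprintf(
    "<incompressibility_fit> r = %.4f, slope = %.3f (n = %d %s patches)\n",
    x$r, x$slope, x$n, if (x$weighted) "area-weighted" else "unweighted"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.incompressibility_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r", "slope", "intercept"),
    estimate = c(x$r, x$slope, x$intercept)
  )
}

#' @export
glance.incompressibility_fit <- function(x, ...) {
  tibble::tibble(r = x$r, slope = x$slope, n = x$n,
                 residual_rms = x$residual_rms, weighted = x$weighted)
}

#' Metric-rate identity check on parametric sequences
#'
#' On an axisymmetric parametric sequence the rate of change of the induced
#' metric must equal the symmetrized covariant velocity gradient minus
#' `2 * vn * b_ij` (second fundamental form, inward normal). Both sides are
#' evaluated semi-analytically on a dense material grid (closed-form radius
#' profile; high-order finite differences along the material coordinate)
#' and the maximum relative deviation is returned.
#'
#' @param seq a parametric [surface_sequence()] from
#'   [make_constricting_tube()] or [make_sphere_sequence()].
#' @param t_index timepoint at which to check (compared against
#'   `t_index + 1` for the time derivative).
#' @return list with `max_rel_dev` and the per-component deviation tibble.
#' @export
metric_rate_check <- function(seq, t_index) {
  kind <- attr(seq, "parametric")
  if (is.null(kind)) stop("metric_rate_check is only supported on parametric sequences")
  if (kind == "sphere") {
    an <- attr(seq, "analytic")
    R <- an$R[t_index]; Rdot <- an$Rdot[t_index]
    # g_ij = R^2 ghat_ij ; dt g = (2 Rdot / R) g ; rhs = -2 vn b = 2 Rdot/R g
    lhs <- 2 * Rdot / R
    vn <- -Rdot
    rhs <- -2 * vn * (1 / R)     # per unit metric: b_ij = g_ij / R (inward)
    dev <- abs(lhs - rhs) / max(abs(lhs), 1e-12)
    return(list(max_rel_dev = dev,
                detail = tibble::tibble(component = "conformal", lhs = lhs,
                                        rhs = rhs)))
  }
  spec <- attr(seq, "spec")
  an <- attr(seq, "analytic")
  a0 <- an[an$t == seq$time[t_index], ]
  a1 <- an[an$t == seq$time[t_index + 1], ]
  dt <- seq$time[t_index + 1] - seq$time[t_index]
  u <- a0$u
  du <- u[2] - u[1]
  d1 <- function(x) {  # centered first derivative along u, one-sided ends
    n <- length(x)
    c((x[2] - x[1]) / du,
      (x[3:n] - x[1:(n - 2)]) / (2 * du),
      (x[n] - x[n - 1]) / du)
  }
  g_of <- function(a) {
    zu <- d1(a$z); ru <- d1(a$r)
    list(guu = zu^2 + ru^2, gpp = a$r^2, zu = zu, ru = ru)
  }
  g0 <- g_of(a0); g1 <- g_of(a1)
  # midpoint-in-time comparison
  lhs_uu <- (g1$guu - g0$guu) / dt
  lhs_pp <- (g1$gpp - g0$gpp) / dt
  mid <- function(x0, x1) (x0 + x1) / 2
  z <- mid(a0$z, a1$z); r <- mid(a0$r, a1$r)
  zu <- d1(z); ru <- d1(r)
  guu <- zu^2 + ru^2; gpp <- r^2
  vz <- mid(a0$vz, a1$vz); vr <- mid(a0$vr, a1$vr)
  vn <- mid(a0$vn, a1$vn)
  # covariant component of the tangential velocity along u
  vu <- vz * zu + vr * ru - vn * 0  # v . X_u ; (normal part is orthogonal to X_u)
  # inward normal in the (radial, axial) plane: (-1, rz)/sqrt(1+rz^2) with
  # rz = ru/zu along the profile
  rz <- ru / zu
  sq <- sqrt(1 + rz^2)
  # second fundamental form (inward normal):
  # X_uu . n_in and X_phiphi . n_in
  zuu <- d1(zu); ruu <- d1(ru)
  n_r <- -1 / sq; n_z <- rz / sq
  b_uu <- ruu * n_r + zuu * n_z
  b_pp <- -r * n_r               # X_phiphi = (-r cos, -r sin, 0); dot n_in
  # christoffels of diag metric
  guu_u <- d1(guu); gpp_u <- d1(gpp)
  nab_u_vu <- d1(vu) - 0.5 * (guu_u / guu) * vu
  nab_p_vp <- 0.5 * (gpp_u / guu) * vu
  rhs_uu <- 2 * nab_u_vu - 2 * vn * b_uu
  rhs_pp <- 2 * nab_p_vp - 2 * vn * b_pp
  # trim the ends where one-sided differences lose accuracy
  keep <- 3:(length(u) - 2)
  scale_uu <- max(abs(lhs_uu[keep]), abs(rhs_uu[keep]), 1e-12)
  scale_pp <- max(abs(lhs_pp[keep]), abs(rhs_pp[keep]), 1e-12)
  detail <- tibble::tibble(
    u = u[keep],
    dev_uu = (lhs_uu - rhs_uu)[keep] / scale_uu,
    dev_pp = (lhs_pp - rhs_pp)[keep] / scale_pp
  )
  list(max_rel_dev = max(abs(c(detail$dev_uu, detail$dev_pp))), detail = detail)
}
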