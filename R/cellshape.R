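# Cell-scale measurements: embedding segmented polygons on the surface,
# shape tensors in the local tangent frame, area-weighted statistics with
# bootstrap standard errors, single-cell area tracking, T1 detection, and
# the comparisons used for mutant analysis.

# Second moments of area of a simple polygon about its centroid
# (shoelace formulas). Returns area (positive), centroid, and the 2x2
# moment tensor (Ixx, Ixy, Iyy).
polygon_moments <- function(x, y) {
  n <- length(x)
  xi <- x; yi <- y
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  cr <- xi * yj - xj * yi
  A <- sum(cr) / 2
  if (A < 0) {  # enforce counterclockwise
    x <- rev(x); y <- rev(y)
    xi <- x; yi <- y; xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
    cr <- xi * yj - xj * yi
    A <- sum(cr) / 2
  }
  cx <- sum((xi + xj) * cr) / (6 * A)
  cy <- sum((yi + yj) * cr) / (6 * A)
  Ixx <- sum((xi^2 + xi * xj + xj^2) * cr) / 12 - A * cx^2
  Iyy <- sum((yi^2 + yi * yj + yj^2) * cr) / 12 - A * cy^2
  Ixy <- sum((xi * yj + 2 * xi * yi + 2 * xj * yj + xj * yi) * cr) / 24 - A * cx * cy
  list(area = A, cx = cx, cy = cy, Ixx = Ixx, Ixy = Ixy, Iyy = Iyy)
}

# TRUE if the polygon has a pair of properly crossing edges
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  ccw <- function(ax, ay, bx, by, cx, cy) (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- seg[i, ]; b <- seg[j, ]
      if (ccw(a[1], a[2], b[1], b[2], b[3], b[4]) != ccw(a[3], a[4], b[1], b[2], b[3], b[4]) &&
          ccw(a[1], a[2], a[3], a[4], b[1], b[2]) != ccw(a[1], a[2], a[3], a[4], b[3], b[4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Exact area of the image of a chart polygon under the piecewise-linear
# surface map: the polygon is clipped against every overlapping mesh face
# (Sutherland-Hodgman in chart space) and each clipped piece weighted by
# that face's 3D/chart area Jacobian.
chart_area_measurer <- function(surface) {
  uv <- face_chart_uv(surface)
  fg <- face_geometry(surface)
  tri_chart_area <- abs((uv$u2[, 1] - uv$u1[, 1]) * (uv$u3[, 2] - uv$u1[, 2]) -
                        (uv$u3[, 1] - uv$u1[, 1]) * (uv$u2[, 2] - uv$u1[, 2])) / 2
  J <- fg$area / tri_chart_area
  smin <- pmin(uv$u1[, 1], uv$u2[, 1], uv$u3[, 1])
  smax <- pmax(uv$u1[, 1], uv$u2[, 1], uv$u3[, 1])
  pmin_f <- pmin(uv$u1[, 2], uv$u2[, 2], uv$u3[, 2])
  pmax_f <- pmax(uv$u1[, 2], uv$u2[, 2], uv$u3[, 2])
  function(s, phi) {
    total <- 0
    for (shift in c(-2 * pi, 0, 2 * pi)) {
      px <- s
      py <- phi + shift
      cand <- which(smin <= max(px) & smax >= min(px) &
                    pmin_f <= max(py) & pmax_f >= min(py))
      for (f in cand) {
        a <- clip_area_tri(px, py, uv$u1[f, ], uv$u2[f, ], uv$u3[f, ])
        total <- total + a * J[f]
      }
    }
    total
  }
}

# area of a polygon clipped to a triangle (both in 2D)
clip_area_tri <- function(px, py, t1, t2, t3) {
  # ensure counterclockwise triangle
  if ((t2[1] - t1[1]) * (t3[2] - t1[2]) - (t3[1] - t1[1]) * (t2[2] - t1[2]) < 0) {
    tmp <- t2; t2 <- t3; t3 <- tmp
  }
  edges <- list(c(t1, t2), c(t2, t3), c(t3, t1))
  x <- px; y <- py
  for (e in edges) {
    n <- length(x)
    if (n == 0) return(0)
    ex <- e[3] - e[1]; ey <- e[4] - e[2]
    side <- ex * (y - e[2]) - ey * (x - e[1])   # >= 0 is inside (ccw)
    nx <- ny <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      in_i <- side[i] >= 0; in_j <- side[j] >= 0
      if (in_i) { nx <- c(nx, x[i]); ny <- c(ny, y[i]) }
      if (xor(in_i, in_j)) {
        t <- side[i] / (side[i] - side[j])
        nx <- c(nx, x[i] + t * (x[j] - x[i]))
        ny <- c(ny, y[i] + t * (y[j] - y[i]))
      }
    }
    x <- nx; y <- ny
  }
  if (length(x) < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Locate chart points in the surface triangulation and interpolate 3D
# positions barycentrically. Points are (s, phi); faces straddling the phi
# seam are handled by testing the point at phi and phi + 2*pi.
chart_locator <- function(surface) {
  uv <- face_chart_uv(surface)
  u1 <- uv$u1; u2 <- uv$u2; u3 <- uv$u3
  smin <- pmin(u1[, 1], u2[, 1], u3[, 1])
  smax <- pmax(u1[, 1], u2[, 1], u3[, 1])
  v <- surface$vertices
  f <- surface$faces
  function(s, phi) {
    n <- length(s)
    out <- matrix(NA_real_, n, 3)
    fidx <- integer(n)
    for (q in seq_len(n)) {
      cand <- which(smin <= s[q] + 1e-9 & smax >= s[q] - 1e-9)
      hit <- NA_integer_
      lam <- NULL
      for (ph in c(phi[q] %% (2 * pi), phi[q] %% (2 * pi) + 2 * pi)) {
        a1 <- u1[cand, , drop = FALSE]
        a2 <- u2[cand, , drop = FALSE]
        a3 <- u3[cand, , drop = FALSE]
        d <- (a2[, 2] - a3[, 2]) * (a1[, 1] - a3[, 1]) +
             (a3[, 1] - a2[, 1]) * (a1[, 2] - a3[, 2])
        l1 <- ((a2[, 2] - a3[, 2]) * (s[q] - a3[, 1]) +
               (a3[, 1] - a2[, 1]) * (ph - a3[, 2])) / d
        l2 <- ((a3[, 2] - a1[, 2]) * (s[q] - a3[, 1]) +
               (a1[, 1] - a3[, 1]) * (ph - a3[, 2])) / d
        l3 <- 1 - l1 - l2
        ok <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
        if (length(ok) > 0) {
          hit <- cand[ok[1]]
          lam <- c(l1[ok[1]], l2[ok[1]], l3[ok[1]])
          break
        }
      }
      if (is.na(hit)) stop(sprintf("chart point (s = %.3g, phi = %.3g) outside the surface chart", s[q], phi[q]))
      out[q, ] <- lam[1] * v[f[hit, 1], ] + lam[2] * v[f[hit, 2], ] + lam[3] * v[f[hit, 3], ]
      fidx[q] <- hit
    }
    list(xyz = out, face = fidx)
  }
}

#' Embed segmented cell polygons and measure their shape tensors
#'
#' Each polygon, given in chart coordinates, is embedded in 3D by
#' barycentric interpolation over the surface triangulation, projected onto
#' the local tangent plane at its centroid, and measured by the second
#' moment of area tensor expressed in the local `(s_hat, phi_hat)` frame.
#' The aspect ratio is `a/b = sqrt(I1 / I2)` (eigenvalues `I1 >= I2`) and
#' the orientation `theta` is the angle of the major axis from `s_hat`,
#' in `(-pi/2, pi/2]`.
#'
#' @param polygons tibble with columns `cell_id`, `s`, `phi` (vertices in
#'   order; one polygon per `cell_id`), and optionally `time`.
#' @param surface a [tube_surface()] with chart.
#' @param densify number of extra points interpolated along each polygon
#'   edge in chart space before embedding (default 1), so that cells large
#'   relative to the surface curvature still follow the surface.
#' @return A tibble of class `cell_shape_records`: `cell_id`, `time`,
#'   `area` (embedded 3D polygon area, square micrometres), `aspect`, `theta`,
#'   `I1`, `I2`, `s`, `phi` (centroid chart position), `cx`, `cy`, `cz`
#'   (3D centroid).
#' @export
embed_and_measure <- function(polygons, surface, densify = 1L) {
  polygons <- tibble::as_tibble(polygons)
  if (!"time" %in% names(polygons)) polygons$time <- 0
  locate <- chart_locator(surface)
  measure_area <- chart_area_measurer(surface)
  td <- tangent_directions(surface)
  keys <- dplyr::distinct(polygons, cell_id, time)
  res <- purrr::pmap(keys, function(cell_id, time) {
    p <- polygons[polygons$cell_id == cell_id & polygons$time == time, ]
    # unwrap phi along the polygon
    dphi <- diff(p$phi)
    dphi <- atan2(sin(dphi), cos(dphi))
    phiu <- p$phi[1] + c(0, cumsum(dphi))
    if (polygon_self_intersects(p$s, phiu)) {
      stop("self-intersecting polygon for cell_id ", cell_id, " at time ", time)
    }
    su <- p$s
    if (densify > 0) {
      fr <- seq(0, 1, length.out = densify + 2)[-(densify + 2)]
      k <- length(su)
      nxt <- c(2:k, 1)
      su <- as.vector(t(outer(su, 1 - fr) + outer(su[nxt], fr)))
      phiu <- as.vector(t(outer(phiu, 1 - fr) + outer(phiu[nxt], fr)))
    }
    loc <- locate(su, phiu)
    P <- loc$xyz
    cen <- colMeans(P)
    # tangent frame at the centroid's containing face
    cphi <- atan2(mean(sin(phiu)), mean(cos(phiu)))
    cface <- tryCatch(locate(mean(p$s), cphi)$face, error = function(e) loc$face[1])
    fr <- td[cface, ]
    sh <- c(fr$s_hat_x, fr$s_hat_y, fr$s_hat_z)
    ph <- c(fr$phi_hat_x, fr$phi_hat_y, fr$phi_hat_z)
    x <- as.numeric((P - matrix(cen, nrow(P), 3, byrow = TRUE)) %*% sh)
    y <- as.numeric((P - matrix(cen, nrow(P), 3, byrow = TRUE)) %*% ph)
    # area of the cell's footprint on the (piecewise-linear) surface,
    # exact under the surface map, so it stays faithful in high-curvature
    # regions where the tangent-plane projection shrinks; the shape tensor
    # uses the projected polygon
    a3 <- measure_area(su, phiu)
    m <- polygon_moments(x, y)
    M <- matrix(c(m$Ixx, m$Ixy, m$Ixy, m$Iyy), 2)
    ev <- eigen(M, symmetric = TRUE)
    I1 <- ev$values[1]; I2 <- ev$values[2]
    vec <- ev$vectors[, 1]
    theta <- atan2(vec[2], vec[1])
    if (theta <= -pi / 2) theta <- theta + pi
    if (theta > pi / 2) theta <- theta - pi
    tibble::tibble(
      cell_id = cell_id, time = time, area = a3,
      aspect = sqrt(pmax(I1, 0) / pmax(I2, .Machine$double.eps)),
      theta = theta, I1 = I1, I2 = I2,
      s = mean(p$s), phi = cphi %% (2 * pi),
      cx = cen[1], cy = cen[2], cz = cen[3]
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("cell_shape_records", class(out))
  out
}

#' Area-weighted mean aspect ratio and orientation
#'
#' The mean aspect ratio weights each cell by its area,
#' `<a/b> = sum(A_i (a/b)_i) / sum(A_i)`, so every material point counts
#' equally. The mean orientation is the two-argument arctangent of the
#' area-weighted vector sum,
#' `<theta> = atan2(sum(A_i sin theta_i), sum(A_i cos theta_i))`; with
#' `axial = TRUE` angles are doubled before averaging and halved after,
#' the usual treatment for orientations defined modulo pi.
#'
#' @param records a `cell_shape_records` tibble (or any tibble with
#'   `aspect`/`theta` and `area`).
#' @param axial use doubled-angle axial statistics for the orientation?
#' @return scalar mean.
#' @export
weighted_mean_aspect <- function(records) {
  A <- records$area
  if (all(A == 0)) stop("all cell areas are zero")
  sum(A * records$aspect) / sum(A)
}

#' @rdname weighted_mean_aspect
#' @export
weighted_mean_orientation <- function(records, axial = FALSE) {
  A <- records$area
  if (all(A == 0)) stop("all cell areas are zero")
  th <- records$theta
  if (axial) {
    m <- atan2(sum(A * sin(2 * th)), sum(A * cos(2 * th))) / 2
  } else {
    m <- atan2(sum(A * sin(th)), sum(A * cos(th)))
  }
  m
}

#' Bootstrap standard error of the weighted mean
#'
#' Subsamples of size `n` are drawn with replacement for 50 values of `n`
#' between `N/4` and `N`; the variance of the subsample means is fit by
#' least squares to `sigma^2(n) = a / n + b`, and the fit evaluated at
#' `n = N` gives the squared standard error. This extrapolation removes the
#' bias a plain n-out-of-N bootstrap inherits from weighting; in practice
#' the two agree closely.
#'
#' @param values numeric vector of per-cell values.
#' @param weights weights (cell areas); equal by default.
#' @param n_boot bootstrap replicates per subsample size.
#' @param n_sizes number of subsample sizes (default 50).
#' @param seed integer seed.
#' @return the standard error (scalar), with the fitted variance curve in
#'   attribute `"fit"`.
#' @export
bootstrap_se <- function(values, weights = NULL, n_boot = 1000, n_sizes = 50, seed = 1L) {
  N <- length(values)
  if (N < 8) stop("bootstrap_se needs at least 8 observations")
  if (is.null(weights)) weights <- rep(1, N)
  set.seed(seed)
  sizes <- unique(round(seq(ceiling(N / 4) + 1, N, length.out = n_sizes)))
  vars <- vapply(sizes, function(n) {
    idx <- matrix(sample.int(N, n * n_boot, replace = TRUE), n_boot, n)
    wm <- matrix(weights[idx], n_boot, n)
    vm <- matrix(values[idx], n_boot, n)
    stats::var(rowSums(wm * vm) / rowSums(wm))
  }, numeric(1))
  fit <- stats::lm(vars ~ I(1 / sizes))
  v_at_N <- sum(stats::coef(fit) * c(1, 1 / N))
  se <- sqrt(max(v_at_N, 0))
  attr(se, "fit") <- tibble::tibble(n = sizes, var = vars,
                                    fitted = stats::fitted(fit))
  se
}

#' Per-track cell area time series
#'
#' @param records `cell_shape_records` with consistent `cell_id` tracks
#'   across `time`.
#' @return list with `tracks` (tibble `cell_id`, `time`, `area`,
#'   `rel_area` = area / first area) and `summary` (per-time mean, sd of
#'   `rel_area`, and n). Gaps in a track are tolerated and flagged in
#'   attribute `"gaps"`.
#' @export
track_cell_areas <- function(records) {
  if (anyDuplicated(records[, c("cell_id", "time")])) {
    stop("duplicate (cell_id, time) record(s)")
  }
  tr <- records |>
    dplyr::arrange(cell_id, time) |>
    dplyr::group_by(cell_id) |>
    dplyr::mutate(rel_area = area / area[1]) |>
    dplyr::ungroup() |>
    dplyr::select(cell_id, time, area, rel_area)
  times <- sort(unique(tr$time))
  gaps <- tr |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(n < length(times))
  summary <- tr |>
    dplyr::group_by(time) |>
    dplyr::summarise(mean_rel_area = mean(rel_area), sd_rel_area = stats::sd(rel_area),
                     n = dplyr::n(), .groups = "drop")
  out <- list(tracks = tr, summary = summary)
  attr(out, "gaps") <- gaps$cell_id
  out
}

#' Detect T1 neighbor exchanges
#'
#' Takes the per-timepoint adjacency of tracked cells, drops pairs that are
#' neighbors at every timepoint, debounces flicker (adjacency states held
#' for `debounce` timepoints or fewer revert to the surrounding state), and
#' reports one event per remaining adjacency change. If cell centroids are
#' supplied the axis of each event (the centroid-to-centroid direction of
#' the pair, relative to the AP axis of the local patch coordinates) is
#' attached.
#'
#' @param adjacency tibble with columns `time`, `cell_a`, `cell_b`
#'   (unordered pairs present = adjacent at that time).
#' @param centroids optional tibble `cell_id`, `time`, `u`, `v` in a
#'   locally conformal patch (AP along `u`).
#' @param debounce flicker window in timepoints (default 1).
#' @param times full vector of observed timepoints; defaults to the times
#'   present in `adjacency` (supply explicitly if some timepoint has no
#'   adjacent pairs at all).
#' @return tibble of class `t1_events`: `kind` ("gained"/"lost"), `time`,
#'   `cell_a`, `cell_b`, `axis_deg` (NA without centroids).
#' @export
detect_t1_events <- function(adjacency, centroids = NULL, debounce = 1L,
                             times = NULL) {
  adjacency <- tibble::as_tibble(adjacency)
  a <- pmin(adjacency$cell_a, adjacency$cell_b)
  b <- pmax(adjacency$cell_a, adjacency$cell_b)
  adjacency$pair <- paste(a, b, sep = "|")
  if (is.null(times)) times <- sort(unique(adjacency$time))
  if (length(times) < 2) stop("need at least 2 timepoints")
  events <- list()
  for (pr in unique(adjacency$pair)) {
    present <- times %in% adjacency$time[adjacency$pair == pr]
    if (all(present)) next  # never rearranges
    state <- debounce_states(present, debounce)
    ch <- which(diff(state) != 0)
    cells <- as.numeric(strsplit(pr, "|", fixed = TRUE)[[1]])
    for (k in ch) {
      events[[length(events) + 1]] <- tibble::tibble(
        kind = if (state[k + 1]) "gained" else "lost",
        time = times[k + 1], cell_a = cells[1], cell_b = cells[2]
      )
    }
  }
  out <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(kind = character(), time = numeric(),
                   cell_a = numeric(), cell_b = numeric())
  out$axis_deg <- NA_real_
  if (!is.null(centroids) && nrow(out) > 0) {
    for (i in seq_len(nrow(out))) {
      ca <- centroids[centroids$cell_id == out$cell_a[i] & centroids$time == out$time[i], ]
      cb <- centroids[centroids$cell_id == out$cell_b[i] & centroids$time == out$time[i], ]
      if (nrow(ca) == 1 && nrow(cb) == 1) {
        ang <- atan2(cb$v - ca$v, cb$u - ca$u) * 180 / pi
        ang <- ((ang + 90) %% 180) - 90   # fold to (-90, 90]
        out$axis_deg[i] <- ang
      }
    }
  }
  class(out) <- c("t1_events", class(out))
  out
}

# merge runs of length <= debounce into the surrounding state
debounce_states <- function(state, debounce) {
  if (debounce < 1) return(state)
  r <- rle(state)
  while (length(r$lengths) > 2) {
    short <- which(r$lengths <= debounce)
    short <- short[short > 1 & short < length(r$lengths)]
    if (length(short) == 0) break
    r$values[short[1]] <- r$values[short[1] - 1]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

#' Orientation bias of T1 events
#'
#' Events whose pair axis lies within 45 degrees of the AP axis are
#' classified as AP-oriented (DV-converging), the rest as DV-oriented;
#' an exact two-sided binomial test against equal frequencies follows.
#'
#' @param events a `t1_events` tibble with `axis_deg`.
#' @return list with `n_ap`, `n_dv`, `p_value`.
#' @export
t1_orientation_bias <- function(events) {
  ax <- events$axis_deg[!is.na(events$axis_deg)]
  if (length(ax) < 1) stop("no events with axis information")
  n_ap <- sum(abs(ax) <= 45)
  n_dv <- length(ax) - n_ap
  list(n_ap = n_ap, n_dv = n_dv,
       p_value = stats::binom.test(n_ap, n_ap + n_dv, 0.5)$p.value)
}

#' Compare cell-shape change with tissue shear
#'
#' Joins the per-s-bin time series of mean cell anisotropy against the
#' tissue anisotropy ratio `K` from the shear kymograph (same material
#' s-bins) and reports their pooled Pearson correlation.
#'
#' @param records `cell_shape_records` over time with centroid `s`.
#' @param kymo a [shear_kymograph()] tibble.
#' @return list with `table` (per bin and time: mean cell aspect, tissue K)
#'   and `correlation`.
#' @export
cellshape_vs_tissue_shear <- function(records, kymo) {
  if (length(intersect(unique(records$time), unique(kymo$t))) == 0) {
    stop("records and kymograph share no timepoints")
  }
  br <- sort(unique(kymo$s_mid))
  half <- diff(br[1:2]) / 2
  edges <- c(br - half, br[length(br)] + half)
  tab <- records |>
    dplyr::filter(time %in% unique(kymo$t)) |>
    dplyr::mutate(s_bin = pmin(pmax(findInterval(s, edges), 1), length(br))) |>
    dplyr::group_by(time, s_bin) |>
    dplyr::summarise(cell_aspect = sum(area * aspect) / sum(area),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(kymo, by = c("time" = "t", "s_bin")) |>
    dplyr::select(time, s_bin, s_mid, cell_aspect, K, n)
  list(table = tab,
       correlation = stats::cor(tab$cell_aspect, tab$K))
}

#' Relative motion of paired nuclei across layers
#'
#' Computes the 3D separation of muscle-endoderm nucleus pairs over time,
#' the population mean and SD, a linear fit of the mean separation (rate in
#' micrometres/hour), and the integrated per-nucleus path length for
#' comparison: tightly tethered layers show separations growing much more
#' slowly than the tissue travels.
#'
#' @param tracks tibble `pair_id`, `layer`, `time` (min), `x`, `y`, `z`;
#'   two layers per pair, matched at every timepoint.
#' @return list of class `pair_motion`: `separation` (per pair, time),
#'   `summary` (per time: mean, sd), `rate_um_per_h`, `mean_path_um`,
#'   `mean_delta_separation_um`.
#' @export
nuclei_pair_motion <- function(tracks) {
  tracks <- tibble::as_tibble(tracks)
  wide <- tidyr::pivot_wider(tracks, id_cols = c(pair_id, time),
                             names_from = layer, values_from = c(x, y, z))
  nm <- names(wide)
  layers <- unique(tracks$layer)
  if (length(layers) != 2) stop("tracks must contain exactly two layers")
  if (anyNA(wide)) stop("unpaired track: some pair is missing one layer at some time")
  l1 <- layers[1]; l2 <- layers[2]
  sep <- sqrt((wide[[paste0("x_", l1)]] - wide[[paste0("x_", l2)]])^2 +
              (wide[[paste0("y_", l1)]] - wide[[paste0("y_", l2)]])^2 +
              (wide[[paste0("z_", l1)]] - wide[[paste0("z_", l2)]])^2)
  sep_tb <- tibble::tibble(pair_id = wide$pair_id, time = wide$time, separation = sep)
  summary <- sep_tb |>
    dplyr::group_by(time) |>
    dplyr::summarise(mean_sep = mean(separation), sd_sep = stats::sd(separation),
                     .groups = "drop")
  fit <- stats::lm(mean_sep ~ time, data = summary)
  rate <- unname(stats::coef(fit)[2]) * 60
  # integrated path length per nucleus
  path <- tracks |>
    dplyr::arrange(pair_id, layer, time) |>
    dplyr::group_by(pair_id, layer) |>
    dplyr::summarise(path = sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)),
                     .groups = "drop")
  dsep <- sep_tb |>
    dplyr::group_by(pair_id) |>
    dplyr::summarise(d = abs(separation[dplyr::n()] - separation[1]), .groups = "drop")
  out <- list(separation = sep_tb, summary = summary,
              rate_um_per_h = rate,
              mean_path_um = mean(path$path),
              mean_delta_separation_um = mean(dsep$d))
  class(out) <- "pair_motion"
  out
}

#' @export
print.pair_motion <- function(x, ...) {
  cat(sprintf("<pair_motion> %d pairs; separation rate %.2f um/h; mean path %.1f um vs mean |dsep| %.1f um\n",
              length(unique(x$separation$pair_id)), x$rate_um_per_h,
              x$mean_path_um, x$mean_delta_separation_um))
  invisible(x)
}

#' Compare cell anisotropy between two conditions over time
#'
#' At each shared timepoint the area-weighted mean aspect ratio of each
#' condition is summarized (mean, bootstrap SE as SD of the mean, cell
#' count) and compared with the two-sample z-score; a sustained one-sided
#' p-value combines the per-timepoint Z values by Stouffer's method.
#'
#' @param records_a,records_b `cell_shape_records` for the two conditions.
#' @param seed seed for the bootstrap SEs.
#' @return list with `per_time` (tibble `time`, `mean_a`, `mean_b`,
#'   `se_a`, `se_b`, `z`, `p`) and `sustained_p`.
#' @export
group_anisotropy_comparison <- function(records_a, records_b, seed = 1L) {
  shared <- intersect(unique(records_a$time), unique(records_b$time))
  if (length(shared) == 0) stop("conditions share no timepoints")
  if (length(shared) == 1) warning("single shared timepoint; sustained p not meaningful")
  rows <- purrr::map(sort(shared), function(tt) {
    ra <- records_a[records_a$time == tt, ]
    rb <- records_b[records_b$time == tt, ]
    se_a <- as.numeric(bootstrap_se(ra$aspect, ra$area, n_boot = 200, seed = seed))
    se_b <- as.numeric(bootstrap_se(rb$aspect, rb$area, n_boot = 200, seed = seed + 1L))
    ga <- group_summary(weighted_mean_aspect(ra), se_a * sqrt(nrow(ra)), nrow(ra))
    gb <- group_summary(weighted_mean_aspect(rb), se_b * sqrt(nrow(rb)), nrow(rb))
    z <- z_score(gb, ga)    # mutant minus control
    tibble::tibble(time = tt, mean_a = ga$mean, mean_b = gb$mean,
                   se_a = se_a, se_b = se_b, z = z, p = one_sided_p(z))
  })
  per_time <- dplyr::bind_rows(rows)
  z_comb <- sum(per_time$z) / sqrt(nrow(per_time))
  list(per_time = per_time, sustained_p = one_sided_p(z_comb),
       combined_z = z_comb)
}
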