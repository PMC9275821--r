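# Synthetic cell tessellations: circumferentially elongated cells on a tube
# chart, built as a brick-wall (combinatorially hexagonal) tessellation with
# shared jittered vertices, so polygons stay simple, non-overlapping and
# periodic in phi.

#' Specification of a synthetic cell field
#'
#' @param n_cells approximate number of cells to generate.
#' @param mean_area target mean cell area (square micrometres).
#' @param aspect_profile target aspect ratio `a/b >= 1`: a constant or a
#'   function of the axial coordinate `s`.
#' @param orientation cell long-axis orientation in radians from the
#'   circumferential axis (0 = circumferentially elongated).
#' @param jitter dimensionless vertex jitter (fraction of cell size).
#' @param seed integer seed.
#' @return object of class `cell_field_spec`.
#' @export
cell_field_spec <- function(n_cells = 600, mean_area = 60,
                            aspect_profile = 2.5, orientation = 0,
                            jitter = 0.1, seed = 7L) {
  stopifnot(mean_area > 0, n_cells >= 4, jitter >= 0)
  prof <- if (is.function(aspect_profile)) aspect_profile else {
    val <- aspect_profile
    function(s) rep(val, length(s))
  }
  if (any(prof(c(0, 50, 100)) < 1)) stop("aspect_profile must be >= 1 everywhere")
  structure(list(n_cells = as.integer(n_cells), mean_area = mean_area,
                 aspect_profile = prof, orientation = orientation,
                 jitter = jitter, seed = as.integer(seed)),
            class = "cell_field_spec")
}

#' Generate a cell tessellation on a tube surface
#'
#' Cells are laid out in the chart's arc-length plane `(s, y)` (with
#' `y = r * phi` the circumferential arc) as a brick-wall tessellation:
#' columns along `s` with alternate columns offset by half a row, making
#' every cell a right-angled hexagon with shared vertices. A column at
#' axial position `s` is `h / aspect_profile(s)` wide while all rows are
#' `h` tall, so cells realize the target aspect ratio with circumferential
#' orientation; shared vertices are then jittered (periodically in `y`)
#' and a nonzero `orientation` rotates each cell about its centroid.
#' `n_cells` is matched approximately: the row count follows from
#' `mean_area` and the circumference, and columns fill the tube length.
#'
#' @param spec a [cell_field_spec()].
#' @param surface a [tube_surface()] with chart.
#' @return list with `polygons` (tibble `cell_id`, `s`, `phi`, vertex rows
#'   in order) and `truth` (tibble `cell_id`, `s_center`, `target_aspect`,
#'   `orientation`).
#' @export
make_cell_tessellation <- function(spec, surface) {
  stopifnot(inherits(spec, "cell_field_spec"))
  if (is.null(surface$chart)) stop("surface needs a chart")
  set.seed(spec$seed)
  ch <- surface$chart
  s_rng <- range(ch$s)
  L <- diff(s_rng)
  n_hoops <- max(4, min(50, floor(L / 4), floor(length(unique(ch$s)) / 2)))
  cl <- centerline(surface, n_hoops = n_hoops)
  v <- surface$vertices
  cl_xyz <- cbind(
    stats::approx(cl$s_mid, cl$x, xout = ch$s, rule = 2, ties = "ordered")$y,
    stats::approx(cl$s_mid, cl$y, xout = ch$s, rule = 2, ties = "ordered")$y,
    stats::approx(cl$s_mid, cl$z, xout = ch$s, rule = 2, ties = "ordered")$y)
  rad_v <- sqrt(rowSums((v - cl_xyz)^2))
  r_of_s <- function(s) stats::approx(ch$s, rad_v, xout = s, rule = 2, ties = "ordered")$y
  C <- 2 * pi * mean(rad_v)
  asp_mid <- mean(spec$aspect_profile(seq(s_rng[1], s_rng[2], length.out = 64)))
  # cell area = h * w = h^2 / aspect  =>  h = sqrt(mean_area * aspect)
  h <- sqrt(spec$mean_area * asp_mid)
  n_rows <- max(4L, round(C / h))
  h <- C / n_rows
  # column edges: width h / aspect(s) advancing along s
  cols <- s_rng[1]
  xs <- s_rng[1]
  while (xs < s_rng[2] - 1e-9) {
    xs <- min(xs + h / spec$aspect_profile(xs), s_rng[2])
    cols <- c(cols, xs)
  }
  # merge a sliver end column (narrower than half a regular column) so
  # vertex jitter cannot collapse it
  n <- length(cols)
  if (n > 2 && diff(cols[(n - 1):n]) < 0.5 * h / spec$aspect_profile(cols[n - 1])) {
    cols <- cols[-(n - 1)]
  }
  n_cols <- length(cols) - 1
  if (n_cols * n_rows < spec$n_cells / 2) {
    stop("n_cells too large for mean_area on this surface")
  }
  # shared jittered vertices: a vertex lives on column line k (x = cols[k+1])
  # at half-row index m (y = m * h / 2), periodic with period 2 * n_rows
  jit <- spec$jitter * min(h, h / asp_mid)
  env <- new.env()
  vert <- function(k, m) {
    mm <- ((m %% (2 * n_rows)) + 2 * n_rows) %% (2 * n_rows)
    key <- paste(k, mm)
    got <- env[[key]]
    if (is.null(got)) {
      xj <- if (k > 0 && k < n_cols) stats::rnorm(1, 0, jit) else 0
      got <- c(cols[k + 1] + xj, mm * h / 2 + stats::rnorm(1, 0, jit))
      env[[key]] <- got
    }
    c(got[1], got[2] + floor(m / (2 * n_rows)) * C)
  }
  polys <- vector("list", n_cols * n_rows)
  truth <- vector("list", n_cols * n_rows)
  cid <- 0
  for (k in seq_len(n_cols)) {
    parity <- k %% 2              # column offset in half rows
    for (j in seq_len(n_rows)) {
      cid <- cid + 1
      m0 <- 2 * (j - 1) + parity  # bottom edge half-row index
      pts <- rbind(
        vert(k - 1, m0),          # bottom-left
        vert(k,     m0),          # bottom-right
        vert(k,     m0 + 1),      # right mid (T vertex)
        vert(k,     m0 + 2),      # top-right
        vert(k - 1, m0 + 2),      # top-left
        vert(k - 1, m0 + 1)       # left mid (T vertex)
      )
      polys[[cid]] <- tibble::tibble(cell_id = cid, s = pts[, 1], y = pts[, 2])
      sc <- (cols[k] + cols[k + 1]) / 2
      truth[[cid]] <- tibble::tibble(
        cell_id = cid, s_center = sc,
        target_aspect = spec$aspect_profile(sc),
        orientation = spec$orientation
      )
    }
  }
  pol <- dplyr::bind_rows(polys)
  tru <- dplyr::bind_rows(truth)
  if (spec$orientation != 0) {
    th <- spec$orientation
    pol <- pol |>
      dplyr::group_by(cell_id) |>
      dplyr::mutate(
        sc = mean(s), yc = mean(y),
        s2 = sc + cos(th) * (s - sc) - sin(th) * (y - yc),
        y2 = yc + sin(th) * (s - sc) + cos(th) * (y - yc)
      ) |>
      dplyr::ungroup() |>
      dplyr::transmute(cell_id, s = s2, y = y2)
  }
  pol$phi <- (pol$y / r_of_s(pol$s)) %% (2 * pi)
  pol$s <- pmin(pmax(pol$s, s_rng[1]), s_rng[2])
  list(polygons = dplyr::select(pol, cell_id, s, phi), truth = tru)
}
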