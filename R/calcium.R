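# Calcium-transient quantification from frame triplets: the triplet
# difference statistic, feature extraction, AP activity profiles,
# per-embryo normalization and group kymographs.

#' Transient activity of a frame triplet
#'
#' `dI = |I1 - I2| + |I2 - I3| + |I1 - I3|`, pixelwise: zero for static
#' frames, large where a transient pulse appears in a subset of the
#' triplet. Symmetric under any permutation of the frames.
#'
#' @param I1,I2,I3 equal-shape numeric matrices (maximum-intensity
#'   projections taken seconds apart).
#' @return matrix `dI >= 0`.
#' @export
transient_activity <- function(I1, I2, I3) {
  if (!all(dim(I1) == dim(I2)) || !all(dim(I2) == dim(I3))) {
    stop("frame shape mismatch")
  }
  abs(I1 - I2) + abs(I2 - I3) + abs(I1 - I3)
}

#' Per-triplet transient activity of a calcium stack
#'
#' @param stack a `calcium_stack`.
#' @return list of `dI` matrices, one per triplet.
#' @export
stack_transient_activity <- function(stack) {
  n_tr <- dim(stack$frames)[3] / 3
  lapply(seq_len(n_tr), function(tr) {
    k <- (tr - 1) * 3
    transient_activity(stack$frames[, , k + 1], stack$frames[, , k + 2],
                       stack$frames[, , k + 3])
  })
}

#' Extract coherent features from a transient-activity image
#'
#' Gaussian blur followed by a white top-hat filter (opening subtracted),
#' which suppresses smooth background plateaus while keeping isolated
#' pulse blobs.
#'
#' @param dI transient-activity matrix.
#' @param blur_sigma Gaussian blur SD in pixels (default 2).
#' @param tophat_radius top-hat structuring disc radius in pixels
#'   (default 15); should exceed the blur support.
#' @return cleaned matrix (non-negative).
#' @export
extract_features <- function(dI, blur_sigma = 2, tophat_radius = 15) {
  stopifnot(blur_sigma > 0, tophat_radius > 0)
  if (tophat_radius < 2 * blur_sigma) {
    warning("tophat_radius below the blur support; features may be erased")
  }
  # pad by edge replication so blur and morphology see no artificial border
  pad <- ceiling(tophat_radius) + ceiling(3 * blur_sigma)
  ny <- nrow(dI); nx <- ncol(dI)
  ri <- c(rep(1, pad), seq_len(ny), rep(ny, pad))
  ci <- c(rep(1, pad), seq_len(nx), rep(nx, pad))
  # EBImage grayscale morphology assumes intensities in [0, 1]
  scale <- max(dI, 1e-12)
  img <- EBImage::Image(dI[ri, ci] / scale)
  bl <- EBImage::gblur(img, sigma = blur_sigma)
  brush <- EBImage::makeBrush(2 * floor(tophat_radius) + 1, shape = "disc")
  th <- EBImage::whiteTopHat(bl, brush)
  out <- pmax(as.matrix(EBImage::imageData(th)), 0) * scale
  out[pad + seq_len(ny), pad + seq_len(nx)]
}

#' Anterior-posterior activity profile
#'
#' Sums the cleaned transient signal along the circumferential image axis.
#'
#' @param dI matrix (rows = circumferential, columns = AP by default).
#' @param ap_axis `"col"` (default) or `"row"`: which image axis is AP.
#' @param pixel_size micrometres per pixel.
#' @return tibble `ap_um`, `value`.
#' @export
ap_activity_profile <- function(dI, ap_axis = c("col", "row"), pixel_size = 1) {
  ap_axis <- match.arg(ap_axis)
  v <- if (ap_axis == "col") colSums(dI) else rowSums(dI)
  tibble::tibble(ap_um = (seq_along(v) - 1) * pixel_size, value = v)
}

#' Activity profiles for every triplet of a stack
#'
#' @param stack a `calcium_stack`.
#' @param blur_sigma,tophat_radius passed to [extract_features()].
#' @param clean apply [extract_features()] first (default TRUE)?
#' @return tibble `triplet`, `t_min` (time of the triplet start, minutes),
#'   `ap_um`, `value`.
#' @export
stack_activity_profiles <- function(stack, blur_sigma = 2, tophat_radius = 15,
                                    clean = TRUE) {
  dIs <- stack_transient_activity(stack)
  rows <- purrr::imap(dIs, function(dI, tr) {
    if (clean) dI <- extract_features(dI, blur_sigma, tophat_radius)
    pr <- ap_activity_profile(dI, pixel_size = stack$pixel_size)
    pr$triplet <- tr
    pr$t_min <- stack$time_s[(tr - 1) * 3 + 1] / 60
    pr
  })
  dplyr::bind_rows(rows)[, c("triplet", "t_min", "ap_um", "value")]
}

#' Time-integrated activity
#'
#' @param profiles tibble from [stack_activity_profiles()].
#' @param window `c(t_start, t_end)` in minutes (default: everything).
#' @return tibble `ap_um`, `integrated` (sum of per-triplet values whose
#'   `t_min` falls in the window).
#' @export
integrate_activity <- function(profiles, window = NULL) {
  if (!is.null(window)) {
    if (window[1] > max(profiles$t_min) || window[2] < min(profiles$t_min)) {
      stop("integration window outside the recorded time range")
    }
    profiles <- profiles[profiles$t_min >= window[1] & profiles$t_min <= window[2], ]
  }
  profiles |>
    dplyr::group_by(ap_um) |>
    dplyr::summarise(integrated = sum(value), .groups = "drop")
}

#' Normalize an activity profile across embryos
#'
#' `dI -> (dI - dI_bg) / (dI_max - dI_bg)`: the background level is the
#' mean over AP positions within the background window (far from the
#' constriction site), the maximum over the whole profile; background maps
#' to 0 and the peak to 1, cancelling embryo-to-embryo intensity scale.
#'
#' @param profile tibble `ap_um`, `value` (e.g. integrated activity with
#'   `value = integrated`).
#' @param bg_window `c(min_um, max_um)` distances from `site_um` defining
#'   the background region (default 45-50 micrometres).
#' @param site_um AP position of the putative constriction.
#' @return the profile tibble with a `normalized` column; background and
#'   max in attributes `"bg"` and `"max"`.
#' @export
normalize_embryo <- function(profile, site_um, bg_window = c(45, 50)) {
  val <- if ("normalized" %in% names(profile)) profile$normalized else
    if ("integrated" %in% names(profile)) profile$integrated else profile$value
  d <- abs(profile$ap_um - site_um)
  bg_sel <- d >= bg_window[1] & d <= bg_window[2]
  if (!any(bg_sel)) stop("no AP positions inside the background window")
  bg <- mean(val[bg_sel])
  mx <- max(val)
  if (mx <= bg) stop("profile maximum does not exceed background (uninformative record)")
  profile$normalized <- (val - bg) / (mx - bg)
  attr(profile, "bg") <- bg
  attr(profile, "max") <- mx
  profile
}

#' Group-mean activity kymograph
#'
#' Aligns per-embryo profile series by their constriction-onset times,
#' interpolates onto a common `(AP, t)` grid and reports mean and SEM
#' layers.
#'
#' @param profile_list list of tibbles from [stack_activity_profiles()]
#'   (one per embryo).
#' @param onset_min numeric vector of alignment times `t = 0` (minutes),
#'   one per embryo.
#' @param n_t,n_ap grid resolution.
#' @return tibble of class `activity_kymograph`: `t_min`, `ap_um`, `mean`,
#'   `sem`, `n`.
#' @export
activity_kymograph <- function(profile_list, onset_min, n_t = 20, n_ap = 40) {
  stopifnot(length(profile_list) == length(onset_min))
  aligned <- purrr::map2(profile_list, onset_min, function(p, t0) {
    p$t_min <- p$t_min - t0
    p
  })
  ap_lo <- max(vapply(aligned, function(p) min(p$ap_um), numeric(1)))
  ap_hi <- min(vapply(aligned, function(p) max(p$ap_um), numeric(1)))
  if (ap_lo >= ap_hi) stop("embryos share no AP range")
  t_lo <- max(vapply(aligned, function(p) min(p$t_min), numeric(1)))
  t_hi <- min(vapply(aligned, function(p) max(p$t_min), numeric(1)))
  ap_grid <- seq(ap_lo, ap_hi, length.out = n_ap)
  t_grid <- seq(t_lo, t_hi, length.out = n_t)
  vals <- array(NA_real_, c(n_t, n_ap, length(aligned)))
  for (e in seq_along(aligned)) {
    p <- aligned[[e]]
    tt <- sort(unique(p$t_min))
    mat <- vapply(tt, function(ti) {
      pi <- p[p$t_min == ti, ]
      stats::approx(pi$ap_um, pi$value, xout = ap_grid, rule = 2,
                    ties = "ordered")$y
    }, numeric(n_ap))
    for (a in seq_len(n_ap)) {
      vals[, a, e] <- stats::approx(tt, mat[a, ], xout = t_grid, rule = 2,
                                    ties = "ordered")$y
    }
  }
  out <- tidyr::expand_grid(t_min = t_grid, ap_um = ap_grid)
  m <- apply(vals, c(1, 2), mean)                       # n_t x n_ap
  s <- apply(vals, c(1, 2), stats::sd) / sqrt(dim(vals)[3])
  out$mean <- as.vector(t(m))                           # ap fastest, matching the grid
  out$sem <- as.vector(t(s))
  out$n <- length(aligned)
  class(out) <- c("activity_kymograph", class(out))
  out
}
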