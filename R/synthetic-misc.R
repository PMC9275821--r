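# Remaining synthetic inputs: paired nuclei tracks, pulsed calcium movies,
# and Bernoulli fold-outcome tables.

#' Generate paired muscle-endoderm nuclei tracks
#'
#' Each pair shares a common tissue trajectory (smooth large-scale motion
#' on a tube undergoing constriction-like displacements) plus an initial
#' separation below 5 micrometres; the two layers then drift apart at
#' `drift_rate` along the initial separation direction, with isotropic
#' Gaussian tracking noise added independently per timepoint. The tissue
#' motion makes the integrated path length much larger than the relative
#' drift, as for tightly tethered layers.
#'
#' @param n_pairs number of pairs (the reference cohort used 81).
#' @param drift_rate relative drift in micrometres/hour (>= 0).
#' @param duration total time in minutes.
#' @param dt sampling interval (minutes).
#' @param noise_sd tracking noise SD per coordinate (micrometres).
#' @param seed integer seed.
#' @return tibble `pair_id`, `layer` ("muscle"/"endoderm"), `time`, `x`,
#'   `y`, `z`; attribute `"truth"` holds the per-pair initial separation
#'   and drift direction.
#' @export
make_nuclei_pairs <- function(n_pairs = 81, drift_rate = 5, duration = 60,
                              dt = 1, noise_sd = 0.3, seed = 11L) {
  stopifnot(drift_rate >= 0, duration > 0, dt > 0)
  set.seed(seed)
  times <- seq(0, duration, by = dt)
  R0 <- 30; L0 <- 200
  rows <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    s0 <- stats::runif(1, 0.1 * L0, 0.9 * L0)
    ph0 <- stats::runif(1, 0, 2 * pi)
    # smooth tissue motion: inward radial pull near a constriction plus
    # axial advection, a few tens of micrometres over an hour
    amp_r <- stats::runif(1, 5, 12)
    amp_z <- stats::runif(1, 8, 20)
    freq <- stats::runif(1, 0.5, 1.5)
    base <- cbind(
      (R0 - amp_r * (1 - cos(pi * times / max(times))) / 2 *
         exp(-(s0 - L0 / 2)^2 / (2 * 40^2))) * cos(ph0),
      (R0 - amp_r * (1 - cos(pi * times / max(times))) / 2 *
         exp(-(s0 - L0 / 2)^2 / (2 * 40^2))) * sin(ph0),
      s0 + amp_z * sin(freq * pi * times / max(times)) * (s0 / L0 - 0.5)
    )
    d0_len <- stats::runif(1, 1, 4.5)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    drift_per_min <- drift_rate / 60
    sep_vec <- outer(d0_len + drift_per_min * times, dir)
    muscle <- base + matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base))
    endo <- base + sep_vec + matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base))
    rows[[p]] <- dplyr::bind_rows(
      tibble::tibble(pair_id = p, layer = "muscle", time = times,
                     x = muscle[, 1], y = muscle[, 2], z = muscle[, 3]),
      tibble::tibble(pair_id = p, layer = "endoderm", time = times,
                     x = endo[, 1], y = endo[, 2], z = endo[, 3])
    )
    truth[[p]] <- tibble::tibble(pair_id = p, d0 = d0_len,
                                 dir_x = dir[1], dir_y = dir[2], dir_z = dir[3])
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Specification of a synthetic calcium movie
#'
#' Frames come in triplets separated by `triplet_interval` seconds, one
#' triplet per composite period; transient pulses are Gaussian blobs over a
#' noisy background, localized at the given anterior-posterior positions.
#'
#' @param frame_shape `c(n_rows, n_cols)` pixels; columns are the AP axis.
#' @param n_triplets number of frame triplets.
#' @param triplet_interval seconds between the frames of a triplet (9-10 s).
#' @param composite_period seconds between triplets (default 90).
#' @param pulse_centers AP positions of pulse sites (micrometres).
#' @param pulse_rate pulses per minute per site.
#' @param amplitude pulse peak intensity above background.
#' @param duration pulse duration in frames (>= 1).
#' @param pulse_sigma blob SD in pixels.
#' @param background_level constant background intensity.
#' @param noise_sd Gaussian pixel noise SD.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(frame_shape = c(64, 128), n_triplets = 20,
                       triplet_interval = 9, composite_period = 90,
                       pulse_centers = 60, pulse_rate = 2,
                       amplitude = 50, duration = 1, pulse_sigma = 3,
                       background_level = 20, noise_sd = 2,
                       pixel_size = 1, seed = 5L) {
  stopifnot(amplitude >= 0, duration >= 1,
            triplet_interval >= 9, triplet_interval <= 10)
  structure(list(frame_shape = as.integer(frame_shape),
                 n_triplets = as.integer(n_triplets),
                 triplet_interval = triplet_interval,
                 composite_period = composite_period,
                 pulse_centers = pulse_centers, pulse_rate = pulse_rate,
                 amplitude = amplitude, duration = as.integer(duration),
                 pulse_sigma = pulse_sigma,
                 background_level = background_level, noise_sd = noise_sd,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "pulse_spec")
}

#' Generate a synthetic calcium movie
#'
#' @param spec a [pulse_spec()].
#' @return object of class `calcium_stack`: list with `frames` (array
#'   `n_rows x n_cols x (3 * n_triplets)`), `time_s` per frame, `triplet`
#'   index per frame, `pixel_size`, and `truth` (tibble of injected pulses:
#'   `triplet`, `frame_in_triplet`, `row`, `col`, `amplitude`).
#' @export
make_calcium_movie <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  set.seed(spec$seed)
  ny <- spec$frame_shape[1]; nx <- spec$frame_shape[2]
  n_frames <- 3L * spec$n_triplets
  frames <- array(spec$background_level, c(ny, nx, n_frames)) +
    array(stats::rnorm(ny * nx * n_frames, 0, spec$noise_sd), c(ny, nx, n_frames))
  time_s <- as.vector(vapply(seq_len(spec$n_triplets) - 1L, function(k) {
    k * spec$composite_period + (0:2) * spec$triplet_interval
  }, numeric(3)))
  triplet <- rep(seq_len(spec$n_triplets), each = 3)
  # expected pulses per site per triplet period
  lam <- spec$pulse_rate * spec$composite_period / 60
  truth <- list()
  if (spec$amplitude > 0) {
    for (cen in spec$pulse_centers) {
      col0 <- cen / spec$pixel_size + 1
      for (tr in seq_len(spec$n_triplets)) {
        n_p <- stats::rpois(1, lam)
        if (n_p == 0) next
        for (q in seq_len(n_p)) {
          f0 <- sample.int(3, 1)
          row0 <- stats::runif(1, 0.2 * ny, 0.8 * ny)
          colj <- col0 + stats::rnorm(1, 0, 1.5)
          blob <- outer(
            exp(-((seq_len(ny) - row0)^2) / (2 * spec$pulse_sigma^2)),
            exp(-((seq_len(nx) - colj)^2) / (2 * spec$pulse_sigma^2))
          ) * spec$amplitude
          for (df in seq_len(spec$duration)) {
            fi <- f0 + df - 1L
            if (fi > 3) break            # pulses stay within their triplet
            frames[, , (tr - 1L) * 3L + fi] <- frames[, , (tr - 1L) * 3L + fi] + blob
          }
          truth[[length(truth) + 1]] <- tibble::tibble(
            triplet = tr, frame_in_triplet = f0, row = row0, col = colj,
            amplitude = spec$amplitude)
        }
      }
    }
  }
  structure(list(
    frames = frames, time_s = time_s, triplet = triplet,
    pixel_size = spec$pixel_size,
    truth = if (length(truth) > 0) dplyr::bind_rows(truth) else
      tibble::tibble(triplet = integer(), frame_in_triplet = integer(),
                     row = numeric(), col = numeric(), amplitude = numeric())
  ), class = "calcium_stack")
}

#' @export
print.calcium_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calcium_stack> %d x %d px, %d frames (%d triplets), %d true pulses\n",
              d[1], d[2], d[3], d[3] / 3, nrow(x$truth)))
  invisible(x)
}

#' Generate Bernoulli fold-outcome tables
#'
#' Each embryo forms all three constrictions with probability `p_true`;
#' failures form 0-2 folds (mostly 1-2, as partial phenotypes dominate).
#'
#' @param p_true success probability in `[0, 1]`.
#' @param N number of embryos.
#' @param seed integer seed.
#' @return tibble `embryo`, `folds` (0-3), `success` (folds == 3).
#' @export
make_fold_outcomes <- function(p_true, N, seed = 3L) {
  stopifnot(p_true >= 0, p_true <= 1, N >= 1)
  set.seed(seed)
  success <- stats::runif(N) < p_true
  folds <- ifelse(success, 3L, sample(0:2, N, replace = TRUE,
                                      prob = c(0.15, 0.45, 0.40)))
  tibble::tibble(embryo = seq_len(N), folds = as.integer(folds),
                 success = folds == 3L)
}
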