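test_that("triplet activity is permutation-symmetric and exact on pulses", {
  set.seed(6)
  I1 <- matrix(runif(100, 0, 50), 10)
  I2 <- matrix(runif(100, 0, 50), 10)
  I3 <- matrix(runif(100, 0, 50), 10)
  ref <- transient_activity(I1, I2, I3)
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  Is <- list(I1, I2, I3)
  for (p in perms) {
    expect_equal(transient_activity(Is[[p[1]]], Is[[p[2]]], Is[[p[3]]]), ref)
  }
  # identical frames: zero
  expect_true(all(transient_activity(I1, I1, I1) == 0))
  # single mid-frame pulse of amplitude A: dI = 2A at pulse pixels
  A <- 7
  base <- matrix(10, 8, 8)
  mid <- base; mid[4, 5] <- 10 + A
  dI <- transient_activity(base, mid, base)
  expect_equal(dI[4, 5], 2 * A)
  expect_equal(sum(dI != 0), 1)
  expect_error(transient_activity(base, mid, matrix(0, 4, 4)), "mismatch")
})

test_that("noise-floor expectation matches the folded-normal value", {
  # independent oracle: Monte Carlo mean of the triplet statistic
  set.seed(14)
  sigma <- 2.5
  n <- 4e5
  dI <- abs(rnorm(n, 0, sigma * sqrt(2))) + abs(rnorm(n, 0, sigma * sqrt(2))) +
    abs(rnorm(n, 0, sigma * sqrt(2)))
  closed_form <- 6 * sigma / sqrt(pi)
  expect_equal(mean(dI), closed_form, tolerance = 0.01)
  # and through the actual operation on images
  I <- array(rnorm(3 * 200 * 200, 0, sigma), c(200, 200, 3))
  expect_equal(mean(transient_activity(I[, , 1], I[, , 2], I[, , 3])),
               closed_form, tolerance = 0.02)
})

test_that("feature extraction keeps blobs and removes smooth background", {
  ny <- 64; nx <- 64
  flat <- matrix(5, ny, nx)
  expect_lt(max(extract_features(flat, 2, 15)), 1e-6)
  # Gaussian blob riding a gradient
  grad <- outer(rep(1, ny), seq(0, 20, length.out = nx))
  blob <- 40 * outer(exp(-((1:ny) - 32)^2 / 18), exp(-((1:nx) - 32)^2 / 18))
  cleaned <- extract_features(grad + blob, 2, 15)
  win <- cleaned[24:40, 24:40]
  expect_gt(sum(win), 0.8 * sum(blob[24:40, 24:40]) * 0.8)
  # background corners strongly suppressed relative to the retained blob
  expect_lt(mean(cleaned[1:10, 50:64]), 0.1 * max(cleaned))
  expect_warning(extract_features(blob, blur_sigma = 10, tophat_radius = 5),
                 "blur support")
})

test_that("AP profiles localize pulses and are flat for uniform activity", {
  mv <- make_calcium_movie(pulse_spec(pulse_centers = 60, n_triplets = 15,
                                      seed = 5))
  pr <- stack_activity_profiles(mv)
  ia <- integrate_activity(pr)
  expect_lt(abs(ia$ap_um[which.max(ia$integrated)] - 60), 5)
  # probing 20 um off the site sees much less signal
  peak <- max(ia$integrated)
  off <- ia$integrated[which.min(abs(ia$ap_um - 80))]
  expect_lt(off, 0.5 * peak)
  # uniform (pulse-free) movie: flat profile
  quiet <- make_calcium_movie(pulse_spec(amplitude = 0, n_triplets = 10, seed = 2))
  iq <- integrate_activity(stack_activity_profiles(quiet))
  expect_lt(sd(iq$integrated) / mean(pmax(iq$integrated, 1e-9)), 2)
  expect_error(integrate_activity(pr, window = c(1e5, 2e5)), "window")
})

test_that("per-embryo normalization maps background to 0, max to 1, and cancels intensity scale", {
  mv <- make_calcium_movie(pulse_spec(pulse_centers = 60, n_triplets = 12, seed = 5))
  pr1 <- stack_activity_profiles(mv)
  ia1 <- integrate_activity(pr1)
  n1 <- normalize_embryo(ia1, site_um = 60)
  expect_equal(max(n1$normalized), 1)
  bg_sel <- abs(n1$ap_um - 60) >= 45 & abs(n1$ap_um - 60) <= 50
  expect_equal(mean(n1$normalized[bg_sel]), 0, tolerance = 1e-9)
  # affine intensity rescaling of the raw movie leaves the result unchanged
  mv2 <- mv
  mv2$frames <- 3.2 * mv$frames + 11
  ia2 <- integrate_activity(stack_activity_profiles(mv2))
  n2 <- normalize_embryo(ia2, site_um = 60)
  expect_equal(n2$normalized, n1$normalized, tolerance = 1e-6)
  # uninformative records fail
  flatp <- tibble::tibble(ap_um = 0:100, value = rep(5, 101))
  expect_error(normalize_embryo(flatp, site_um = 50), "uninformative")
})

test_that("pulse recovery: peak activity sits at the generator's pulse center", {
  for (cen in c(40, 90)) {
    mv <- make_calcium_movie(pulse_spec(pulse_centers = cen, n_triplets = 12,
                                        seed = cen))
    ia <- integrate_activity(stack_activity_profiles(mv))
    expect_lt(abs(ia$ap_um[which.max(ia$integrated)] - cen), 5)
  }
})

test_that("group kymographs align on onset and reflect suppressed mutants", {
  mv1 <- make_calcium_movie(pulse_spec(pulse_centers = 60, n_triplets = 12, seed = 5))
  pr1 <- stack_activity_profiles(mv1)
  # single record: kymograph equals its own profile matrix
  k1 <- activity_kymograph(list(pr1), 0, n_t = 12, n_ap = 16)
  direct <- stats::approx(pr1$ap_um[pr1$triplet == 1],
                          pr1$value[pr1$triplet == 1],
                          xout = sort(unique(k1$ap_um)), rule = 2)$y
  expect_equal(k1$mean[k1$t_min == min(k1$t_min)], direct, tolerance = 1e-6)
  expect_true(all(k1$sem == 0 | is.na(k1$sem)))
  # suppressed, delocalized mutant fixture
  mut <- make_calcium_movie(pulse_spec(pulse_centers = c(20, 60, 100),
                                       amplitude = 8, pulse_rate = 0.5,
                                       n_triplets = 12, seed = 6))
  prm <- stack_activity_profiles(mut)
  kw <- activity_kymograph(list(pr1, pr1), c(0, 0), n_t = 10, n_ap = 16)
  km <- activity_kymograph(list(prm, prm), c(0, 0), n_t = 10, n_ap = 16)
  expect_gt(max(kw$mean), 2 * max(km$mean))
  expect_error(activity_kymograph(list(pr1), c(0, 0)), "length")
})
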