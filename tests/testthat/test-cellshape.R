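test_that("shape tensor recovers analytic ellipses and hexagons", {
  th <- seq(0, 2 * pi, length.out = 65)[1:64]
  # planar second-moment oracle
  m <- tubekin:::polygon_moments(2 * cos(th), sin(th))
  M <- matrix(c(m$Ixx, m$Ixy, m$Ixy, m$Iyy), 2)
  ev <- eigen(M, symmetric = TRUE)$values
  expect_equal(sqrt(ev[1] / ev[2]), 2, tolerance = 1e-3)
  # embedded on a cylinder via the full pipeline, major axis along s
  cyl <- mesh_cylinder(30, 200, 96, 64)
  ellipse <- tibble::tibble(
    cell_id = 1,
    s = 100 + 4 * cos(th),
    phi = (2 * sin(th)) / 30
  )
  rec <- embed_and_measure(ellipse, cyl)
  expect_equal(rec$aspect, 2, tolerance = 5e-3)
  expect_lt(abs(rec$theta), 0.02)            # major axis along s_hat
  # regular hexagon: isotropic
  hx <- seq(0, 2 * pi, length.out = 7)[1:6]
  hexa <- tibble::tibble(cell_id = 1, s = 100 + 3 * cos(hx), phi = 3 * sin(hx) / 30)
  rech <- embed_and_measure(hexa, cyl)
  expect_equal(rech$aspect, 1, tolerance = 5e-3)
})

test_that("shape measurements are invariant under rigid motion of the surface", {
  fx <- cell_records_cyl()
  surf2 <- fx$surface
  surf2$vertices <- rotate_z(surf2$vertices, 0.9) +
    matrix(c(3, -8, 11), nrow(surf2$vertices), 3, byrow = TRUE)
  sub <- fx$tess$polygons[fx$tess$polygons$cell_id %in% 1:40, ]
  r1 <- embed_and_measure(sub, fx$surface)
  r2 <- embed_and_measure(sub, surf2)
  expect_equal(r2$aspect, r1$aspect, tolerance = 1e-9)
  expect_equal(r2$area, r1$area, tolerance = 1e-9)
})

test_that("self-intersecting polygons are rejected with their id", {
  cyl <- mesh_cylinder(30, 200, 48, 32)
  bowtie <- tibble::tibble(cell_id = 99,
                           s = c(95, 105, 95, 105),
                           phi = c(0.1, 0.2, 0.2, 0.1))
  expect_error(embed_and_measure(bowtie, cyl), "99")
})

test_that("area-weighted means follow the printed formulas", {
  rec <- tibble::tibble(area = c(1, 1), aspect = c(1, 3), theta = c(0, 0))
  expect_equal(weighted_mean_aspect(rec), 2)
  rec2 <- tibble::tibble(area = c(1, 3), aspect = c(1, 2), theta = c(0, 0))
  expect_equal(weighted_mean_aspect(rec2), 1.75)
  rec3 <- tibble::tibble(area = c(1, 1), aspect = c(1, 1),
                         theta = c(pi / 3, -pi / 3))
  expect_equal(weighted_mean_orientation(rec3), 0)
  # axially, +60 and -60 degrees are nearest through the 90-degree axis
  expect_equal(abs(weighted_mean_orientation(rec3, axial = TRUE)), pi / 2)
  # equal weights reduce to unweighted means
  set.seed(5)
  rec4 <- tibble::tibble(area = rep(2, 30), aspect = runif(30, 1, 3),
                         theta = runif(30, -1, 1))
  expect_equal(weighted_mean_aspect(rec4), mean(rec4$aspect))
  expect_error(weighted_mean_aspect(tibble::tibble(area = c(0, 0),
                                                   aspect = c(1, 2))),
               "zero")
})

test_that("bootstrap SE matches sigma/sqrt(N) and the plain bootstrap", {
  set.seed(31)
  x <- rnorm(400)
  se <- as.numeric(bootstrap_se(x, n_boot = 400, seed = 2))
  expect_equal(se, 1 / 20, tolerance = 0.15)
  # plain N-out-of-N bootstrap cross-check
  plain <- sd(replicate(1000, mean(sample(x, replace = TRUE))))
  expect_equal(se, plain, tolerance = 0.1)
  # constant data
  expect_equal(as.numeric(bootstrap_se(rep(3, 50), seed = 1, n_boot = 100)), 0,
               tolerance = 1e-8)
  expect_error(bootstrap_se(1:5), "at least 8")
})

test_that("bootstrap SE scales as 1/sqrt(N)", {
  set.seed(77)
  Ns <- c(100, 400, 1600)
  ses <- vapply(Ns, function(N) {
    as.numeric(bootstrap_se(rnorm(N), n_boot = 300, seed = 4))
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(Ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("cell areas stay constant under the incompressible flow", {
  seq <- small_tube_seq()
  spec <- cell_field_spec(n_cells = 120, mean_area = 250, aspect_profile = 1,
                          jitter = 0.05, seed = 3)
  tess <- make_cell_tessellation(spec, seq$surfaces[[1]])
  # advect: same material chart coordinates embedded on each timepoint
  recs <- dplyr::bind_rows(lapply(seq_along(seq$time), function(k) {
    p <- tess$polygons
    p$time <- seq$time[k]
    embed_and_measure(p, seq$surfaces[[k]])
  }))
  ta <- track_cell_areas(recs)
  expect_lt(max(abs(ta$tracks$rel_area - 1)), 0.01)
  # duplicate records are rejected
  expect_error(track_cell_areas(dplyr::bind_rows(recs, recs[1, ])), "duplicate")
})

test_that("prescribed slow area growth is recovered", {
  base <- tibble::tibble(cell_id = rep(1:50, 5),
                         time = rep(seq(0, 80, by = 20), each = 50))
  set.seed(8)
  base$area <- 30 * (1 + 0.3 * base$time / 80) * exp(rnorm(nrow(base), 0, 0.01))
  ta <- track_cell_areas(base)
  growth <- ta$summary$mean_rel_area[nrow(ta$summary)] - 1
  expect_equal(growth, 0.3, tolerance = 0.03)
})

test_that("the scripted quartet swap yields one gain and one loss with perpendicular axes", {
  times <- 1:4
  persistent <- tidyr::expand_grid(time = times,
                                   tibble::tibble(cell_a = c(1, 1, 2, 2),
                                                  cell_b = c(3, 4, 3, 4)))
  redpink <- tibble::tibble(time = 1:2, cell_a = 3, cell_b = 4)
  bluegreen <- tibble::tibble(time = 3:4, cell_a = 1, cell_b = 2)
  adj <- dplyr::bind_rows(persistent, redpink, bluegreen)
  cent <- tidyr::expand_grid(time = times,
                             tibble::tibble(cell_id = 1:4,
                                            u = c(0, 0, -1, 1),
                                            v = c(1, -1, 0, 0)))
  ev <- detect_t1_events(adj, cent)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$kind, c("gained", "lost"))
  gained <- ev[ev$kind == "gained", ]
  lost <- ev[ev$kind == "lost", ]
  expect_equal(gained$time, 3)
  expect_equal(lost$time, 3)
  dang <- abs(abs(gained$axis_deg - lost$axis_deg) - 90)
  expect_lt(dang, 15)
})

test_that("T1 detection is exact on randomized fixtures and ignores flicker", {
  set.seed(21)
  times <- 1:12
  pairs <- tibble::tibble(cell_a = 1:20, cell_b = 21:40,
                          switch = sample(4:9, 20, replace = TRUE),
                          gain = sample(c(TRUE, FALSE), 20, replace = TRUE))
  adj <- dplyr::bind_rows(lapply(seq_len(20), function(i) {
    pr <- pairs[i, ]
    tt <- if (pr$gain) times[times >= pr$switch] else times[times < pr$switch]
    tibble::tibble(time = tt, cell_a = pr$cell_a, cell_b = pr$cell_b)
  }))
  ev <- detect_t1_events(adj)
  expect_equal(nrow(ev), 20)
  ord <- order(ev$cell_a)
  expect_equal(ev$time[ord], pairs$switch)
  expect_equal(ev$kind[ord] == "gained", pairs$gain)
  # static graph: no events
  static <- tidyr::expand_grid(time = times,
                               tibble::tibble(cell_a = 1:3, cell_b = 4:6))
  expect_equal(nrow(detect_t1_events(static)), 0)
  # one-timepoint flicker is debounced away
  flick <- tidyr::expand_grid(time = times[-6],
                              tibble::tibble(cell_a = 1, cell_b = 2))
  expect_equal(nrow(detect_t1_events(flick, debounce = 1, times = times)), 0)
  expect_gt(nrow(detect_t1_events(flick, debounce = 0, times = times)), 0)
})

test_that("T1 orientation bias test behaves at the extremes", {
  allap <- tibble::tibble(kind = "gained", time = 1, cell_a = 1, cell_b = 2,
                          axis_deg = rep(10, 20))
  expect_lt(t1_orientation_bias(allap)$p_value, 1e-5)
  split <- tibble::tibble(kind = "gained", time = 1, cell_a = 1, cell_b = 2,
                          axis_deg = c(rep(10, 10), rep(80, 10)))
  expect_equal(t1_orientation_bias(split)$p_value, 1)
})

test_that("cell shape change tracks tissue shear for advected cells", {
  seq <- small_tube_seq()
  spec <- cell_field_spec(n_cells = 150, mean_area = 200, aspect_profile = 1,
                          jitter = 0.05, seed = 13)
  tess <- make_cell_tessellation(spec, seq$surfaces[[1]])
  recs <- dplyr::bind_rows(lapply(seq_along(seq$time), function(k) {
    p <- tess$polygons
    p$time <- seq$time[k]
    embed_and_measure(p, seq$surfaces[[k]])
  }))
  mc <- material_chart(seq)
  ky <- shear_kymograph(seq, mc, n_s_bins = 8)
  cmp <- cellshape_vs_tissue_shear(recs, ky)
  expect_gt(cmp$correlation, 0.95)
  # shuffled cells decorrelate
  set.seed(2)
  recs_sh <- recs
  recs_sh$s <- sample(recs_sh$s)
  cmp_sh <- cellshape_vs_tissue_shear(recs_sh, ky)
  expect_lt(abs(cmp_sh$correlation), 0.5)
  # disjoint time ranges are an error
  recs_bad <- recs
  recs_bad$time <- recs_bad$time + 1000
  expect_error(cellshape_vs_tissue_shear(recs_bad, ky), "no timepoints")
})

test_that("pair motion separates drift from tissue travel", {
  tr <- make_nuclei_pairs(40, 5, 60, seed = 19)
  pm <- nuclei_pair_motion(tr)
  expect_equal(pm$rate_um_per_h, 5, tolerance = 0.5)
  expect_gt(pm$mean_path_um, 5 * pm$mean_delta_separation_um)
  # unpaired track fails
  broken <- tr[!(tr$pair_id == 1 & tr$layer == "muscle" & tr$time == 30), ]
  expect_error(nuclei_pair_motion(broken), "unpaired")
})

test_that("group anisotropy comparison detects suppressed shape change", {
  set.seed(41)
  times <- seq(0, 70, by = 10)
  mkrec <- function(level_fun) {
    dplyr::bind_rows(lapply(times, function(tt) {
      tibble::tibble(time = tt, aspect = rnorm(60, level_fun(tt), 0.25),
                     area = runif(60, 20, 40))
    }))
  }
  ctrl <- mkrec(function(tt) 2.5 - 0.015 * tt)   # develops over time
  same <- mkrec(function(tt) 2.5 - 0.015 * tt)
  supp <- mkrec(function(tt) 2.5 - 0.015 * tt - 0.4)  # suppressed anisotropy
  cmp0 <- group_anisotropy_comparison(ctrl, same)
  expect_true(all(abs(cmp0$per_time$z) < 4))
  expect_gt(cmp0$sustained_p, 1e-4)
  cmp1 <- group_anisotropy_comparison(ctrl, supp)
  expect_lt(cmp1$sustained_p, 1e-6)
  # swapping the conditions flips the one-sided tail
  cmp2 <- group_anisotropy_comparison(supp, ctrl)
  expect_gt(cmp2$sustained_p, 1 - 1e-6)
})
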