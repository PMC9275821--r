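test_that("static tube (zero depth) has zero motion and zero fields", {
  seq <- make_constricting_tube(tube_spec(
    constrictions = data.frame(center = 100, depth = 0, width = 15),
    n_s = 32, n_phi = 16, n_t = 4))
  for (k in 2:4) {
    expect_equal(seq$surfaces[[k]]$vertices, seq$surfaces[[1]]$vertices,
                 tolerance = 1e-12)
  }
  an <- attr(seq, "analytic")
  expect_true(all(abs(an$vn) < 1e-12))
  expect_true(all(abs(an$div) < 1e-12))
  expect_true(all(abs(an$vz) < 1e-9))
})

test_that("constricting flow conserves band-cell areas to 1e-3 and beyond", {
  seq <- small_tube_seq()
  fa <- sapply(seq$surfaces, face_areas)
  nf <- nrow(fa); half <- nf / 2
  # each structured quad cell = one face from each half of the face list
  quad <- fa[1:half, ] + fa[(half + 1):nf, ]
  drift <- apply(quad, 1, function(x) max(abs(x / x[1] - 1)))
  expect_lt(max(drift), 1e-3)
  # vertex count constant over time
  expect_length(unique(vapply(seq$surfaces, function(s) nrow(s$vertices),
                              integer(1))), 1)
})

test_that("per-triangle split asymmetry shrinks as resolution grows", {
  drift_at <- function(n_s, n_phi) {
    seq <- make_constricting_tube(tube_spec(n_s = n_s, n_phi = n_phi, n_t = 5,
                                            dt = 6))
    fa <- sapply(seq$surfaces, face_areas)
    max(apply(fa, 1, function(x) max(abs(x / x[1] - 1))))
  }
  d1 <- drift_at(32, 16)
  d2 <- drift_at(64, 16)
  d3 <- drift_at(128, 16)
  expect_lt(d2, d1)
  expect_lt(d3, d2)
})

test_that("generator fails loudly when the neck closes", {
  expect_error(tube_spec(constrictions = data.frame(center = 100, depth = 30,
                                                    width = 15)),
               "below R0")
  expect_error(
    make_constricting_tube(tube_spec(
      constrictions = data.frame(center = 100, depth = 29, width = 15),
      n_s = 32, n_phi = 16, n_t = 5)),
    "timestep")
})

test_that("sphere sequences carry exact closed-form fields", {
  # static sphere: zero velocity
  st <- make_sphere_sequence(function(t) 10, n_t = 3, subdiv = 3)
  expect_equal(st$surfaces[[2]]$vertices, st$surfaces[[1]]$vertices)
  expect_equal(enclosed_volume(st$surfaces[[1]]), 4188.79, tolerance = 1e-2)
  # shrinking sphere: residual = 2 Rdot / R
  sh <- make_sphere_sequence(function(t) 10 * (1 - 0.01 * t), n_t = 4, subdiv = 2)
  an <- attr(sh, "analytic")
  expect_equal(an$residual, 2 * an$Rdot / an$R)
  expect_true(all(an$div == 0))
})

test_that("tessellation realizes target isotropy and anisotropy", {
  cyl <- mesh_cylinder(30, 200, n_s = 64, n_phi = 48)
  iso <- make_cell_tessellation(
    cell_field_spec(n_cells = 300, mean_area = 120, aspect_profile = 1,
                    jitter = 0.02, seed = 4), cyl)
  rec_iso <- embed_and_measure(iso$polygons, cyl)
  expect_equal(weighted_mean_aspect(rec_iso), 1, tolerance = 0.05)
  # and no preferred axis: the doubled-angle resultant is short
  resultant <- Mod(sum(rec_iso$area * exp(2i * rec_iso$theta))) / sum(rec_iso$area)
  expect_lt(resultant, 0.3)

  fx <- cell_records_cyl()
  m <- weighted_mean_aspect(fx$records)
  expect_gt(m, 2)                                   # population claim
  expect_equal(m, 2.5, tolerance = 0.1)             # generator contract
  # polygons periodic in phi and simple: measurement succeeded for all cells
  expect_equal(nrow(fx$records), nrow(fx$tess$truth))
})

test_that("s-varying aspect profiles are recovered along the tube", {
  cyl <- mesh_cylinder(30, 200, n_s = 64, n_phi = 48)
  prof <- function(s) 1.3 + 1.5 * exp(-(s - 100)^2 / (2 * 30^2))
  tess <- make_cell_tessellation(
    cell_field_spec(n_cells = 500, mean_area = 80, aspect_profile = prof,
                    jitter = 0.05, seed = 9), cyl)
  rec <- embed_and_measure(tess$polygons, cyl)
  mid <- rec[abs(rec$s - 100) < 25, ]
  ends <- rec[rec$s < 40 | rec$s > 160, ]
  expect_gt(weighted_mean_aspect(mid), weighted_mean_aspect(ends) + 0.5)
})

test_that("tessellation rejects impossible cell counts", {
  cyl <- mesh_cylinder(30, 200, n_s = 32, n_phi = 16)
  expect_error(
    make_cell_tessellation(cell_field_spec(n_cells = 5000, mean_area = 500), cyl),
    "too large")
})

test_that("nuclei pair tracks obey the pairing rule and drift rate", {
  tr <- make_nuclei_pairs(n_pairs = 81, drift_rate = 5, duration = 60, seed = 11)
  expect_equal(length(unique(tr$pair_id)), 81)
  pm <- nuclei_pair_motion(tr)
  s0 <- pm$separation[pm$separation$time == 0, ]
  expect_lt(max(s0$separation), 5)                  # pairing criterion
  expect_equal(pm$rate_um_per_h, 5, tolerance = 0.1)
  # zero drift: stationary separation
  pm0 <- nuclei_pair_motion(make_nuclei_pairs(30, 0, 60, seed = 2))
  expect_lt(abs(pm0$rate_um_per_h), 0.3)
})

test_that("calcium movies contain only what the spec injects", {
  # amplitude zero: background plus noise only
  quiet <- make_calcium_movie(pulse_spec(amplitude = 0, n_triplets = 4, seed = 8))
  expect_equal(nrow(quiet$truth), 0)
  expect_lt(max(abs(quiet$frames - 20)), 6 * 2)     # within 6 noise SDs
  # pulses never leak outside their triplet
  mv <- make_calcium_movie(pulse_spec(n_triplets = 10, duration = 2, seed = 5))
  expect_true(all(mv$truth$frame_in_triplet %in% 1:3))
})

test_that("fold outcome tables honor the Bernoulli model", {
  all3 <- make_fold_outcomes(1, 50, seed = 1)
  expect_true(all(all3$folds == 3))
  expect_equal(proportion_se(mean(all3$success), 50), 0)
  half <- make_fold_outcomes(0.5, 130, seed = 2)
  expect_true(all(half$folds %in% 0:3))
  expect_equal(nrow(half), 130)
  expect_true(all(half$success == (half$folds == 3)))
})

test_that("all generators are byte-reproducible under a fixed seed", {
  expect_identical(make_fold_outcomes(0.4, 40, seed = 7),
                   make_fold_outcomes(0.4, 40, seed = 7))
  expect_identical(make_nuclei_pairs(5, 5, 20, seed = 3),
                   make_nuclei_pairs(5, 5, 20, seed = 3))
  m1 <- make_calcium_movie(pulse_spec(n_triplets = 2, seed = 4))
  m2 <- make_calcium_movie(pulse_spec(n_triplets = 2, seed = 4))
  expect_identical(m1$frames, m2$frames)
  cyl <- mesh_cylinder(30, 100, n_s = 32, n_phi = 24)
  t1 <- make_cell_tessellation(cell_field_spec(n_cells = 150, seed = 6), cyl)
  t2 <- make_cell_tessellation(cell_field_spec(n_cells = 150, seed = 6), cyl)
  expect_identical(t1$polygons, t2$polygons)
})
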