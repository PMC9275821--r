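test_that("lagrangian velocity reproduces scripted motions", {
  cyl <- mesh_cylinder(10, 50, 24, 16)
  # static
  seq_s <- surface_sequence(list(cyl, cyl, cyl), c(0, 1, 2))
  v <- lagrangian_velocity(seq_s, 1)
  expect_true(all(abs(c(v$vx, v$vy, v$vz)) < 1e-12))
  # rigid translation u per step of dt = 2 min
  u <- c(3, -1, 2)
  cyl2 <- cyl
  cyl2$vertices <- cyl$vertices + matrix(u, nrow(cyl$vertices), 3, byrow = TRUE)
  seq_t <- surface_sequence(list(cyl, cyl2), c(0, 2))
  vt <- lagrangian_velocity(seq_t, 1)
  expect_equal(unique(round(vt$vx, 12)), u[1] / 2)
  expect_equal(unique(round(vt$vz, 12)), u[3] / 2)
  expect_error(lagrangian_velocity(seq_t, 5), "timepoint")
})

test_that("discrete velocity matches the generator's analytic velocity", {
  seq <- small_tube_seq()
  k <- 5
  vel <- lagrangian_velocity(seq, k)
  an <- attr(seq, "analytic")
  a_mid <- an[an$t == seq$time[k], ]
  n_phi <- 32
  vz_d <- vel$vz[seq(1, nrow(vel), by = n_phi)]   # one vertex per ring (phi = 0)
  # compare against the analytic axial velocity at the same markers
  expect_equal(vz_d, a_mid$vz, tolerance = 0.1)
  vn_d <- vel$vn[seq(1, nrow(vel), by = n_phi)]
  expect_equal(vn_d, a_mid$vn, tolerance = 0.05)
})

test_that("covariant divergence is exact for uniform stretch and rejects bad input", {
  cyl <- mesh_cylinder(10, 100, 48, 32)
  k <- 0.015
  v <- cbind(0, 0, k * cyl$vertices[, 3])
  dv <- covariant_divergence(cyl, v)
  iv <- setdiff(seq_len(nrow(cyl$vertices)), tubekin:::boundary_vertices(cyl))
  expect_equal(unname(dv[iv]), rep(k, length(iv)), tolerance = 1e-9)
  # non-tangential input fails
  vbad <- v + vertex_normals(cyl) * 0.5
  expect_error(covariant_divergence(cyl, vbad), "not tangential")
})

test_that("discrete divergence theorem holds exactly on chart sub-rectangles", {
  cyl <- mesh_cylinder(10, 100, 48, 32)
  set.seed(42)
  # smooth random tangential field
  th <- atan2(cyl$vertices[, 2], cyl$vertices[, 1])
  zz <- cyl$vertices[, 3]
  amp <- sin(2 * pi * zz / 100) + cos(2 * th)
  phat <- cbind(-sin(th), cos(th), 0)
  zhat <- matrix(c(0, 0, 1), nrow(cyl$vertices), 3, byrow = TRUE)
  v <- amp * phat + 0.5 * cos(2 * pi * zz / 100) * zhat
  dv <- covariant_divergence(cyl, v)
  W <- tubekin:::cotan_laplacian(cyl)$W
  A <- vertex_areas(cyl)
  sel <- which(cyl$chart$s > 20 & cyl$chart$s < 70 & cyl$chart$phi < 4)
  lhs <- sum((dv * A)[sel])
  Wt <- methods::as(methods::as(W, "generalMatrix"), "TsparseMatrix")
  i <- Wt@i + 1L; j <- Wt@j + 1L; w <- Wt@x
  keep <- i < j
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  e <- cyl$vertices[j, ] - cyl$vertices[i, ]
  alpha <- rowSums((v[i, ] + v[j, ]) / 2 * e)
  cut <- xor(i %in% sel, j %in% sel)
  sgn <- ifelse(i %in% sel, 1, -1)
  rhs <- sum((w * alpha * sgn)[cut])
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("rigid motion of a closed surface leaves zero integrated residual", {
  sph <- mesh_icosphere(10, 3)
  u <- c(0.8, -0.5, 0.3)
  sph2 <- sph
  sph2$vertices <- sph$vertices + matrix(u, nrow(sph$vertices), 3, byrow = TRUE)
  seq <- surface_sequence(list(sph, sph2), c(0, 1))
  vel <- lagrangian_velocity(seq, 1)
  mid <- attr(vel, "midpoint")
  H <- mean_curvature(mid)
  A <- vertex_areas(mid)
  vp <- cbind(vel$vpx, vel$vpy, vel$vpz)
  dv <- covariant_divergence(mid, vp, tol = 1e-3)
  resid <- sum(A * (dv - 2 * H * vel$vn))
  scale <- sum(A * abs(2 * H * vel$vn))
  expect_lt(abs(resid) / scale, 1e-3)
})

test_that("shrinking sphere recovers the closed-form residual", {
  sh <- make_sphere_sequence(function(t) 10 * (1 - 0.01 * t), n_t = 3, subdiv = 3)
  vel <- lagrangian_velocity(sh, 1)
  mid <- attr(vel, "midpoint")
  H <- mean_curvature(mid)
  vp <- cbind(vel$vpx, vel$vpy, vel$vpz)
  dv <- covariant_divergence(mid, vp, tol = 1e-3)
  an <- attr(sh, "analytic")
  target <- 2 * an$Rdot[1] / ((an$R[1] + an$R[2]) / 2)  # midpoint radius
  resid <- dv - 2 * H * vel$vn
  expect_equal(mean(resid), target, tolerance = 0.02)
  expect_lt(max(abs(dv)) / abs(target), 0.05)           # div itself ~ 0
})

test_that("area-preserving tube yields near-zero patch residuals and high correlation", {
  seq <- small_tube_seq()
  fl <- incompressibility_fields_sequence(seq, 20, 16)
  expect_true(all(abs(fl$residual) <= 1e-2))
  expect_true(all(abs(fl$dlogA_dt) <= 1e-2))
  expect_lt(sqrt(weighted.mean(fl$dlogA_dt^2, fl$area)), 2e-3)
  fit <- incompressibility_correlation(fl)
  expect_gt(fit$r, 0.97)
  expect_equal(fit$slope, 1, tolerance = 0.05)
  # tidy/glance accessors
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("r", "slope", "intercept"))
  expect_equal(generics::glance(fit)$r, fit$r)
})

test_that("correlation is scale-invariant and collapses for noise", {
  seq <- small_tube_seq()
  fl <- incompressibility_fields_sequence(seq, 10, 8)
  fit0 <- incompressibility_correlation(fl)
  fl2 <- fl
  fl2$div <- fl2$div * 37
  fl2$oop <- fl2$oop * 37
  expect_equal(incompressibility_correlation(fl2)$r, fit0$r, tolerance = 1e-12)
  set.seed(1)
  fl3 <- fl
  fl3$div <- rnorm(nrow(fl3), sd = sd(fl3$div))
  expect_lt(abs(incompressibility_correlation(fl3)$r), 0.2)
  fl4 <- fl
  fl4$div <- rep(1, nrow(fl4))
  expect_error(incompressibility_correlation(fl4), "zero-variance")
})

test_that("patch residual decreases monotonically under space-time refinement", {
  rms_at <- function(n_s, n_phi, dt, n_t) {
    seq <- make_constricting_tube(tube_spec(n_s = n_s, n_phi = n_phi,
                                            n_t = n_t, dt = dt))
    fl <- incompressibility_fields_sequence(seq, 8, 8)
    sqrt(weighted.mean(fl$residual^2, fl$area))
  }
  r <- c(rms_at(32, 16, 8, 4), rms_at(64, 32, 4, 7), rms_at(128, 64, 2, 13))
  expect_lt(r[2], r[1])
  expect_lt(r[3], r[2])
})

test_that("metric-rate identity holds on parametric sequences", {
  sh <- make_sphere_sequence(function(t) 10, n_t = 3, subdiv = 1)
  expect_equal(metric_rate_check(sh, 1)$max_rel_dev, 0)
  shrink <- make_sphere_sequence(function(t) 10 * (1 - 0.01 * t), n_t = 3, subdiv = 1)
  expect_lt(metric_rate_check(shrink, 1)$max_rel_dev, 1e-6)
  seq <- small_tube_seq()
  expect_lt(metric_rate_check(seq, 5)$max_rel_dev, 0.05)
  cyl <- mesh_cylinder(10, 50, 16, 16)
  plain <- surface_sequence(list(cyl, cyl), c(0, 1))
  expect_error(metric_rate_check(plain, 1), "parametric")
})
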