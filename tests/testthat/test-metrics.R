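# Metrics are validated against the analytic-motion generator, whose
# deformation gradients and global measures have closed forms.

motion_mesh <- build_lv_mesh(rat_geo$pre_p, divisions = c(3, 24, 12))

test_that("ejection fraction matches the closed form of a scaling motion", {
  a <- 0.85; b <- 0.9
  mo <- analytic_motion(radial = a, longitudinal = b, t_end = 100)
  res <- motion_result(motion_mesh, mo, times = seq(0, 100, by = 25))
  expect_equal(ejection_fraction(res), 1 - a^2 * b, tolerance = 0.5e-2)
  expect_equal(ejection_fraction(res, t0 = 0, t1 = 25),
               ejection_fraction(res, t0 = 0, t1 = 25))
  # no motion: EF = 0; dilation: EF < 0
  still <- motion_result(motion_mesh, analytic_motion(), times = c(0, 10))
  expect_equal(ejection_fraction(still), 0)
  grow <- motion_result(motion_mesh,
                        analytic_motion(radial = 1.1, t_end = 10),
                        times = c(0, 10))
  expect_lt(ejection_fraction(grow), 0)
})

test_that("wall thickening matches the closed form of a radial motion", {
  # radial thickening factor 1.2 on a wall of thickness about 0.18
  mo <- analytic_motion(radial = 1.2, t_end = 50)
  res <- motion_result(motion_mesh, mo, times = c(0, 50))
  th0 <- as.numeric(wall_thickness(lvemech:::.mesh_at(res, 1), 0.5))
  expect_equal(wall_thickening(res), 0.2 * th0, tolerance = 0.002)
  expect_equal(wall_thickening(res, t0 = 0, t1 = 0 + 0), 0,
               tolerance = 1e-12)
})

test_that("base-apex shortening matches the closed form and sign convention", {
  b <- 0.9
  mo <- analytic_motion(longitudinal = b, t_end = 50)
  res <- motion_result(motion_mesh, mo, times = c(0, 50))
  # 10 percent long-axis contraction of a 0.95 ventricle: -0.095 (shortening)
  expect_equal(base_apex_shortening(res), -0.095, tolerance = 1e-10)
  # pure torsion does not shorten
  tor <- motion_result(motion_mesh, analytic_motion(torsion = 10, t_end = 50),
                       times = c(0, 50))
  expect_lt(abs(base_apex_shortening(tor)), 1e-9)
})

test_that("cylindrical strains reproduce scaling and torsion closed forms", {
  a <- 0.9; gam_deg <- 8
  mo <- analytic_motion(radial = a, torsion = gam_deg, t_end = 100)
  res <- motion_result(motion_mesh, mo, times = c(0, 100))
  ss <- cylindrical_strains(res)
  k <- 2L
  expect_lt(max(abs(ss$E_cc[, k] - (a^2 - 1) / 2), na.rm = TRUE), 1e-12)
  # E_cl = a^2 R gamma / 2 at in-plane radius R (twist per reference z)
  el <- motion_mesh$elems[, 1:4]
  Rr <- sqrt(rowMeans(matrix(motion_mesh$nodes[el, 1], ncol = 4))^2 +
               rowMeans(matrix(motion_mesh$nodes[el, 2], ncol = 4))^2)
  gam <- gam_deg * pi / 180
  closed <- a^2 * Rr * gam / 2
  expect_lt(max(abs(ss$E_cl[, k] - closed), na.rm = TRUE),
            1e-3 * max(closed))
  expect_lt(max(abs(ss$E_cr[, k]), na.rm = TRUE), 1e-12)

  # rigid rotation about the long axis: all strain components vanish
  rig <- motion_result(motion_mesh,
                       analytic_motion(torsion = 0, t_end = 10),
                       times = c(0, 10))
  ssr <- cylindrical_strains(rig)
  expect_lt(max(abs(ssr$E_cc), abs(ssr$E_cl), abs(ssr$E_cr), na.rm = TRUE),
            1e-10)
})

test_that("metrics are invariant under a rigid rotation of all states", {
  mo <- analytic_motion(radial = 0.85, longitudinal = 0.9, torsion = 5,
                        t_end = 50)
  res <- motion_result(motion_mesh, mo, times = c(0, 50))
  # rotate by exactly 90 degrees about the long axis: the four-ray set of
  # the thickness measurement maps onto itself, so all metrics must match
  # to numerical precision
  Rm <- rot_about(c(0, 0, 1), pi / 2)
  rot <- res
  rot$mesh$nodes <- res$mesh$nodes %*% t(Rm)
  rot$nodes <- lapply(res$nodes, function(nn) nn %*% t(Rm))
  rot$F <- lapply(res$F, function(Fm) {
    out <- Fm
    for (i in 1:3) {
      cols <- (3 * (i - 1) + 1):(3 * i)
      out[, cols] <- 0
    }
    # F' = R F R^T computed row-wise
    for (e in seq_len(nrow(Fm))) {
      Fe <- matrix(Fm[e, ], 3, byrow = TRUE)
      out[e, ] <- as.vector(t(Rm %*% Fe %*% t(Rm)))
    }
    out
  })
  expect_equal(ejection_fraction(rot), ejection_fraction(res),
               tolerance = 1e-10)
  expect_lt(abs(wall_thickening(rot) - wall_thickening(res)), 1e-6)
  expect_equal(base_apex_shortening(rot), base_apex_shortening(res),
               tolerance = 1e-10)
})

test_that("regional averaging respects residual subtraction and permutation", {
  mo <- analytic_motion(radial = 0.9, t_end = 50)
  res <- motion_result(motion_mesh, mo, times = c(0, 25, 50))
  ss <- cylindrical_strains(res)
  ra <- regional_average(ss, subtract_residual = FALSE)
  expect_identical(sort(unique(ra$region)), c("apical", "basal", "mid"))
  # constant field: mean equals the constant
  k <- 3L
  expect_equal(unique(round(ra$value[ra$component == "E_cc" &
                                       ra$time == 50], 12)),
               round((0.9^2 - 1) / 2, 12))
  ra0 <- regional_average(ss, subtract_residual = TRUE)
  expect_true(all(ra0$value[ra0$time == 0] == 0))

  # permuting elements leaves the averages unchanged
  perm <- sample(nrow(ss$E_cc))
  ss_p <- ss
  ss_p$E_cc <- ss$E_cc[perm, , drop = FALSE]
  ss_p$E_cl <- ss$E_cl[perm, , drop = FALSE]
  ss_p$E_cr <- ss$E_cr[perm, , drop = FALSE]
  ss_p$thirds <- ss$thirds[perm]
  ss_p$included <- ss$included[perm]
  expect_equal(regional_average(ss_p)$value, regional_average(ss)$value,
               tolerance = 1e-12)
})

test_that("cavity volume from the surface integral matches the closed form over time", {
  # pure scaling motion: V(t) = a(t)^2 b(t) V0, with V0 the analytic
  # truncated-ellipsoid cavity volume
  mo <- analytic_motion(radial = 0.9, longitudinal = 0.85, t_end = 40)
  res <- motion_result(motion_mesh, mo, times = c(0, 20, 40))
  v0 <- res$volumes[1]
  for (k in 2:3) {
    f <- lvemech:::.motion_factors(mo, res$times[k])
    expect_equal(res$volumes[k], f$a^2 * f$b * v0, tolerance = 1e-3)
  }
})
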