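test_that("helix angle satisfies its endpoint, symmetry and shape identities", {
  expect_equal(helix_angle(0, 70, 1), 70)
  expect_equal(helix_angle(1, 70, 1), -70)
  expect_equal(helix_angle(0.5, 53, 2.7), 0)
  expect_equal(helix_angle(0.25, 80, 0.5), 80 * sqrt(0.5))
  # linear for n = 1
  w <- seq(0, 1, by = 0.1)
  expect_equal(helix_angle(w, 60, 1), 60 * (1 - 2 * w))
  # odd symmetry about midwall and monotone decrease, for a parameter sweep
  for (R in c(50, 60, 70, 80)) {
    for (n in c(0.5, 1, 2, 3)) {
      th <- helix_angle(w, R, n)
      expect_equal(th, -rev(th), tolerance = 1e-12)
      expect_true(all(diff(th) <= 1e-12))
    }
  }
  expect_error(helix_angle(-0.1, 70, 1), "\\[0, 1\\]")
  expect_error(fibre_model(95, 1), "\\(0, 90\\]")
})

test_that("sheet-angle models interpolate their endpoints", {
  lin <- sheet_model("linear")
  bim <- sheet_model("bimodal")
  expect_equal(sheet_angle(0.5, lin), 0)
  expect_equal(sheet_angle(0.5, bim), 0) # sigmoid midpoint = mean of endpoints
  expect_equal(sheet_angle(c(0, 1), lin), c(45, -45))
  # sigmoid saturation: within 1 degree of the endo value at w = 0.2
  expect_lt(abs(sheet_angle(0.2, bim) - 45), 1)
  expect_error(sheet_angle(1.2, lin), "\\[0, 1\\]")
  expect_error(sheet_model("linear", beta_endo = 120), "90")
})

test_that("the rule-based family enumerates 4 x 4 models", {
  mods <- rule_based_models()
  expect_length(mods, 16L)
  expect_true("Sn1R70" %in% names(mods))
  expect_true(all(vapply(mods, function(m) m$R > 0 && m$R <= 90 && m$n > 0,
                         logical(1))))
  expect_identical(mods$Sn0.5R70$n, 0.5)
})

test_that("structure rotations reproduce their defining special cases", {
  fr <- fix_lv_frame
  w <- fix_lv_w
  # theta = 0, beta = 0 (via w = 0.5): f = c, s = r, n parallel to l
  sf0 <- build_structure_field(fix_lv, fr, rep(0.5, length(w)),
                               fibre_model(70, 1), sheet_model("linear", 0, 0))
  expect_lt(max(abs(sf0$f - fr$c)), 1e-12)
  expect_lt(max(abs(sf0$s - fr$r)), 1e-12)
  expect_lt(max(abs(abs(rowSums(sf0$n_vec * fr$l)) - 1)), 1e-12)
  expect_equal(range(frame_det(sf0$f, sf0$s, sf0$n_vec)), c(1, 1),
               tolerance = 1e-10)

  # theta = 90 rotates the fibre onto the longitudinal axis
  sf90 <- build_structure_field(fix_lv, fr, rep(0, length(w)),
                                fibre_model(90, 1),
                                sheet_model("linear", 0, 0))
  expect_lt(max(abs(sf90$f - fr$l)), 1e-10)

  # the fibre-circumferential angle equals |theta| for a generic model
  sf <- build_structure_field(fix_lv, fr, w, fibre_model(70, 2))
  expect_lt(max(abs(angular_difference(sf$f, fr$c) - abs(sf$theta))), 1e-8)
})

test_that("frames are orthonormal for rule-based and regional models", {
  regional <- regional_fibre_model(R = seq(40, 85, length.out = 16),
                                   n = rep(c(0.5, 1, 2, 3), 4))
  fibres <- c(rule_based_models(), list(regional = regional))
  sheets <- list(sheet_model("linear"), sheet_model("bimodal"))
  for (fib in fibres) {
    for (sh in sheets) {
      sf <- build_structure_field(fix_lv, fix_lv_frame, fix_lv_w, fib, sh)
      expect_lt(frame_orthonormality_error(sf$f, sf$s, sf$n_vec), 1e-10)
      expect_equal(range(frame_det(sf$f, sf$s, sf$n_vec)), c(1, 1),
                   tolerance = 1e-10)
    }
  }
})

test_that("the 16-region partition is complete and azimuth-equivariant", {
  reg <- partition_regions(fix_lv)
  expect_identical(sort(unique(reg)), 1:16)
  expect_true(all(tabulate(reg, 16) > 0))

  # element at the base on the +x meridian lands in region 1
  el <- fix_lv$elems[, 1:4]
  cx <- rowMeans(matrix(fix_lv$nodes[el, 1], ncol = 4))
  cy <- rowMeans(matrix(fix_lv$nodes[el, 2], ncol = 4))
  cz <- rowMeans(matrix(fix_lv$nodes[el, 3], ncol = 4))
  base_x <- which.min(abs(cz + 0.02) + abs(atan2(cy, cx) - 0.1))
  expect_identical(reg[base_x], 1L)

  # rotating the mesh by one 60-degree sector permutes the basal and mid
  # labels cyclically (apical sectors are 90 degrees wide, so they are
  # checked separately with a 90-degree rotation)
  rot <- fix_lv
  Rm <- rot_about(c(0, 0, 1), pi / 3)
  rot$nodes <- fix_lv$nodes %*% t(Rm)
  reg_rot <- partition_regions(rot)
  ring <- reg <= 12
  expect_identical(sort(tabulate(reg[ring], 12)),
                   sort(tabulate(reg_rot[ring], 12)))
  expected <- ifelse(reg <= 6, (reg %% 6) + 1L,
                     ifelse(reg <= 12, ((reg - 6L) %% 6) + 7L, reg))
  expect_identical(reg_rot[ring], as.integer(expected[ring]))

  rot90 <- fix_lv
  rot90$nodes <- fix_lv$nodes %*% t(rot_about(c(0, 0, 1), pi / 2))
  reg_90 <- partition_regions(rot90)
  apex <- reg >= 13
  expect_identical(sort(tabulate(reg[apex] - 12L, 4)),
                   sort(tabulate(reg_90[apex] - 12L, 4)))
  expect_identical(reg_90[apex], as.integer(13L + (reg[apex] - 13L + 1L) %% 4))
})

test_that("angular difference is a sign-free axial metric", {
  u <- c(1, 0, 0)
  expect_equal(angular_difference(u, u), 0)
  expect_equal(angular_difference(u, -u), 0)
  expect_equal(angular_difference(u, c(0, 1, 0)), 90)
  expect_equal(angular_difference(c(1, 1, 0) / sqrt(2), u), 45,
               tolerance = 1e-10)
  expect_error(angular_difference(u, c(0, 0, 0)), "zero vector")
})

test_that("regional fitting recovers noise-free parameters and is sign-invariant", {
  cfg <- synthetic_fibre_config(fibre_model(70, 1), noise_sd = 0, seed = 3)
  obs <- synth_fibre_observations(fix_lv, fix_lv_frame, fix_lv_w, cfg)
  fit <- fit_regional_fibre_model(fix_lv, fix_lv_frame, fix_lv_w, obs)
  expect_lt(max(abs(fit$R - 70)), 0.5)
  expect_lt(max(abs(fit$n - 1)), 0.05)
  expect_lt(max(fit$residual), 1e-6)

  flipped <- obs$vectors * rep(c(-1, 1), length.out = nrow(obs$vectors))
  fit2 <- fit_regional_fibre_model(fix_lv, fix_lv_frame, fix_lv_w, flipped)
  expect_equal(fit$R, fit2$R, tolerance = 1e-10)
  expect_equal(fit$n, fit2$n, tolerance = 1e-10)
})

test_that("degenerate circumferential observations hit the search boundary", {
  obs <- fix_lv_frame$c # observations exactly circumferential everywhere
  fit <- fit_regional_fibre_model(fix_lv, fix_lv_frame, fix_lv_w, obs)
  expect_true(any(fit$boundary))
  # best achievable rule puts R at the lower grid bound
  expect_true(all(fit$R <= 31))
})

test_that("fitting errors on missing data", {
  obs <- synth_fibre_observations(fix_lv, config = synthetic_fibre_config())
  expect_error(
    fit_regional_fibre_model(fix_lv, fix_lv_frame, fix_lv_w, obs,
                             min_per_region = 10000L),
    "fewer than"
  )
  bad <- obs$vectors * 2
  expect_error(fit_regional_fibre_model(fix_lv, fix_lv_frame, fix_lv_w, bad),
               "unit vectors")
})
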