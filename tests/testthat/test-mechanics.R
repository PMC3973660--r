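test_that("Green-Lagrange strain has its closed forms and objectivity", {
  expect_equal(green_strain(diag(3)), matrix(0, 3, 3))
  lam <- 1.23
  expect_equal(green_strain(lam * diag(3)), (lam^2 - 1) / 2 * diag(3))
  Rm <- rot_about(c(0.2, -1, 0.5), 1.1)
  expect_lt(max(abs(green_strain(Rm))), 1e-12)
  expect_error(green_strain(diag(c(-1, 1, 1))), "positive determinant")
})

test_that("the exponential strain energy matches closed-form evaluations", {
  law <- law_orthotropic()
  expect_equal(strain_energy(matrix(0, 3, 3), law, J = 1), 0)
  E <- diag(c(0.1, 0, 0))
  expect_equal(strain_energy(E, law, J = 1),
               law$C0 / 2 * (exp(6 * 0.01) - 1))
  # transversely isotropic set: swapping sheet and normal leaves W unchanged
  lt <- law_transverse_isotropic()
  set.seed(4)
  Er <- matrix(rnorm(9, 0, 0.05), 3)
  Er <- (Er + t(Er)) / 2
  P <- matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), 3) # swap s and n
  expect_equal(strain_energy(Er, lt), strain_energy(t(P) %*% Er %*% P, lt),
               tolerance = 1e-14)
  # ... and is exactly invariant to any rotation of (s, n) about f
  for (a in c(0.3, 1.2, 2.8)) {
    Rm <- rot_about(c(1, 0, 0), a)
    expect_lt(abs(strain_energy(Er, lt) -
                    strain_energy(t(Rm) %*% Er %*% Rm, lt)), 1e-12)
  }
  expect_error(material_law(b = c(6, 4, 3, 7, 7, 4),
                            symmetry = "transverse_isotropic"), "b_ss = b_nn")
})

test_that("passive stress is the exact derivative of the energy", {
  for (law in list(law_orthotropic(), law_transverse_isotropic())) {
    set.seed(11)
    E <- matrix(rnorm(9, 0, 0.04), 3)
    E <- (E + t(E)) / 2
    S <- passive_stress(E, law)
    expect_equal(S, t(S))
    expect_equal(passive_stress(matrix(0, 3, 3), law, J = 1),
                 matrix(0, 3, 3))
    h <- 1e-6
    Sfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      dE <- matrix(0, 3, 3)
      dE[i, j] <- h
      dE[j, i] <- dE[j, i] + h # diagonal entries receive 2h in total
      Wp <- strain_energy(E + dE, law)
      Wm <- strain_energy(E - dE, law)
      # dW = 2h S_ij for both diagonal and off-diagonal perturbations
      Sfd[i, j] <- Sfd[j, i] <- (Wp - Wm) / (4 * h)
    }
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-6)
  }
})

test_that("doubling the exponents doubles the deviatoric stress in the linear regime", {
  law1 <- material_law(C0 = 0.88, b = c(6, 7, 3, 12, 3, 3), kappa = 1e-12)
  law2 <- material_law(C0 = 0.88, b = 2 * c(6, 7, 3, 12, 3, 3), kappa = 1e-12)
  E <- diag(c(1e-4, -5e-5, 2e-5))
  E[1, 2] <- E[2, 1] <- 3e-5
  S1 <- passive_stress(E, law1, J = 1)
  S2 <- passive_stress(E, law2, J = 1)
  expect_equal(max(abs(S2 - 2 * S1)) / max(abs(S1)), 0, tolerance = 0.01)
})

test_that("active stress acts along the reference fibre only", {
  expect_equal(active_stress(0, c(1, 0, 0)), matrix(0, 3, 3))
  S <- active_stress(35, c(1, 0, 0))
  expect_equal(S[1, 1], 35)
  expect_equal(sum(abs(S)) - S[1, 1], 0)
  f <- c(1, 2, 2) / 3
  expect_equal(sum(diag(active_stress(35, f))), 35, tolerance = 1e-12)
  expect_error(active_stress(-1, c(1, 0, 0)), ">= 0")
})

test_that("zero load gives zero displacement", {
  st <- solve_quasistatic(fix_mech, fix_mech_sf, law_transverse_isotropic())
  expect_lt(max(abs(st$disp)), 1e-10)
  expect_equal(st$J, rep(1, length(st$J)), tolerance = 1e-12)
})

test_that("a homogeneous deformation reproduces the closed-form reaction", {
  w <- wedge_fixture(3, 3, 3, 1, order = 2)
  Fh <- diag(c(1.10, 0.97, 0.95))
  Fh[1, 2] <- 0.02
  X <- w$nodes
  onb <- apply(X, 1, function(p) any(abs(p) < 1e-9) || any(abs(p - 1) < 1e-9))
  idx <- which(onb)
  ub <- t((Fh - diag(3)) %*% t(X[idx, , drop = FALSE]))
  dofs <- c(3 * idx - 2, 3 * idx - 1, 3 * idx)
  vals <- c(ub[, 1], ub[, 2], ub[, 3])
  law <- law_orthotropic()
  sol <- lvemech:::.newton_solve(w, w$structure, law, 0,
                                 numeric(nrow(w$elems)),
                                 list(dofs = dofs, vals = vals), NULL, 0)
  expect_true(sol$ok)
  st <- lvemech:::.mech_state(w, sol)
  expect_lt(max(abs(sweep(st$F, 2, as.vector(t(Fh))))), 1e-10)
  E <- green_strain(Fh)
  P <- Fh %*% (passive_stress(E, law))
  face <- which(abs(X[, 1] - 1) < 1e-9)
  reaction <- sum(sol$residual[3 * face - 2])
  expect_lt(abs(reaction - P[1, 1]) / abs(P[1, 1]), 0.005)
})

test_that("inflation is monotone in pressure and stiffness, nearly incompressible", {
  law <- law_transverse_isotropic()
  v0 <- mesh_volumes(fix_mech)[["cavity"]]
  expect_identical(inflate(fix_mech, fix_mech_sf, law, 0)$nodes,
                   fix_mech$nodes)
  vols <- vapply(c(0.1, 0.3, 0.5), function(p) {
    mesh_volumes(inflate(fix_mech, fix_mech_sf, law, p))[["cavity"]]
  }, numeric(1))
  expect_true(all(diff(c(v0, vols)) > 0))

  stiff <- law_transverse_isotropic(C0 = 2 * 0.88)
  v_stiff <- mesh_volumes(inflate(fix_mech, fix_mech_sf, stiff, 0.5))[["cavity"]]
  expect_lt(v_stiff, vols[3])

  st <- attr(inflate(fix_mech, fix_mech_sf, law, 0.5), "state")
  expect_gt(median(st$J), 0.95)
  expect_lt(median(st$J), 1.05)
  expect_true(all(st$J > 0))
})

test_that("the unloaded-geometry estimate closes on the reference volume", {
  law <- law_transverse_isotropic()
  ref <- fix_mech
  est0 <- estimate_unloaded(ref, fix_mech_sf, law, pressure = 0)
  expect_identical(est0$s, 1)

  est <- estimate_unloaded(ref, fix_mech_sf, law, pressure = 0.4)
  expect_lt(est$s, 1)
  v_ref <- mesh_volumes(ref)[["cavity"]]
  v_post <- mesh_volumes(est$post_p)[["cavity"]]
  expect_lt(abs(v_post - v_ref) / v_ref, 0.02)
  expect_identical(est$pre_p$provenance, "pre-P")
})

test_that("solver frame-indifference: a rotated problem gives rotated displacements", {
  law <- law_transverse_isotropic()
  st <- solve_quasistatic(fix_mech, fix_mech_sf, law,
                          boundary_spec(pressure = 0.3))
  # rotate about the long axis so the base-plane constraint is preserved
  Rm <- rot_about(c(0, 0, 1), 0.9)
  mr <- fix_mech
  mr$nodes <- fix_mech$nodes %*% t(Rm)
  sr <- fix_mech_sf
  sr$f <- fix_mech_sf$f %*% t(Rm)
  sr$s <- fix_mech_sf$s %*% t(Rm)
  sr$n_vec <- fix_mech_sf$n_vec %*% t(Rm)
  str <- solve_quasistatic(mr, sr, law, boundary_spec(pressure = 0.3))
  expect_lt(max(abs(str$disp - st$disp %*% t(Rm))) / max(abs(st$disp)), 1e-5)
})
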