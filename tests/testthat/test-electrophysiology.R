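test_that("the cell model rests, fires fast and converges in dt", {
  # resting stability
  tr <- run_cell(duration = 100, dt = 0.02)
  expect_lt(max(abs(tr$V - (-80))), 0.01)

  # suprathreshold stimulus: V exceeds 0 mV within 5 ms
  stim <- function(t) if (t < 1) 0.5 else 0
  tr1 <- run_cell(duration = 60, dt = 0.01, stim = stim)
  expect_lt(min(tr1$t[tr1$V > 0]), 5)
  # a rodent-like short action potential (tens of ms above -20 mV)
  apd <- diff(range(tr1$t[tr1$V > -20]))
  expect_gt(apd, 30)
  expect_lt(apd, 80)

  # halving dt changes the trajectory endpoint by < 1 percent
  tr2 <- run_cell(duration = 60, dt = 0.005, stim = stim)
  v1 <- tr1$v[nrow(tr1)]
  v2 <- tr2$v[nrow(tr2)]
  expect_lt(abs(v1 - v2) / max(abs(v2), 0.01), 0.01)

  expect_error(step_cell(cell_state(), I_stim = NaN, dt = 0.01), "non-finite")
})

test_that("the conductivity tensor has the prescribed eigenstructure", {
  p <- monodomain_params(sigma_f = 3, sigma_s = 1, sigma_n = 0.5)
  iso <- monodomain_params(sigma_f = 2, sigma_s = 2, sigma_n = 2)
  expect_equal(conductivity_tensor(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), iso),
               2 * diag(3))
  G <- conductivity_tensor(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), p)
  expect_equal(G[1, 1], 3)
  # random orthonormal frame: eigenvalue multiset preserved
  Q <- qr.Q(qr(matrix(c(0.3, -1, 0.2, 2, 0.1, 1, -0.5, 0.4, 2), 3)))
  G2 <- conductivity_tensor(Q[, 1], Q[, 2], Q[, 3], p)
  expect_equal(sort(eigen(G2, symmetric = TRUE)$values), c(0.5, 1, 3),
               tolerance = 1e-10)
  expect_error(conductivity_tensor(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1), p),
               "orthonormal")
})

test_that("a stimulated wedge carries a planar wave with the expected velocity", {
  w <- wedge_fixture(10, 10, 10, 1)
  p <- monodomain_params()
  stim <- stimulus_protocol(predicate = function(pt) pt[, 1] < 0.06)
  res <- solve_monodomain(w, w$structure, p, stim, 35)
  expect_true(all(!is.na(res$activation)))
  expect_true(all(res$activation >= 0))
  cv <- measure_conduction_velocity(res, c(1, 0, 0))
  expect_gt(attr(cv, "r2"), 0.99)
  expect_equal(as.numeric(cv), 0.06, tolerance = 0.03 * 0.06)

  # zero stimulus: the tissue stays at rest
  res0 <- solve_monodomain(w, w$structure, p,
                           stimulus_protocol(amplitude = 0), 15)
  expect_true(all(is.na(res0$activation)))
  expect_lt(max(abs(res0$voltage + 80)), 1e-6)
})

test_that("conduction velocity scales with the square root of conductivity", {
  w <- wedge_fixture(10, 10, 10, 1)
  stim <- stimulus_protocol(predicate = function(pt) pt[, 1] < 0.06)
  p1 <- monodomain_params()
  p4 <- monodomain_params(sigma_f = 4 * p1$sigma_f,
                          sigma_s = 4 * p1$sigma_s,
                          sigma_n = 4 * p1$sigma_n)
  cv1 <- measure_conduction_velocity(
    solve_monodomain(w, w$structure, p1, stim, 35), c(1, 0, 0))
  cv4 <- measure_conduction_velocity(
    solve_monodomain(w, w$structure, p4, stim, 20), c(1, 0, 0))
  expect_equal(as.numeric(cv4) / as.numeric(cv1), 2, tolerance = 0.05 * 2)
})

test_that("identical conductivities give an isotropic wave", {
  w <- wedge_fixture(9, 9, 9, 1)
  p <- monodomain_params(sigma_f = 1.5, sigma_s = 1.5, sigma_n = 1.5)
  cvx <- measure_conduction_velocity(solve_monodomain(
    w, w$structure, p,
    stimulus_protocol(predicate = function(pt) pt[, 1] < 0.07), 40
  ), c(1, 0, 0))
  cvy <- measure_conduction_velocity(solve_monodomain(
    w, w$structure, p,
    stimulus_protocol(predicate = function(pt) pt[, 2] < 0.07), 40
  ), c(0, 1, 0))
  expect_equal(as.numeric(cvx) / as.numeric(cvy), 1, tolerance = 0.02)
})

test_that("splitting reduces to the single-cell trajectory without diffusion", {
  w <- wedge_fixture(4, 4, 4, 1)
  p <- monodomain_params(sigma_f = 1e-12, sigma_s = 1e-12, sigma_n = 1e-12)
  stim <- stimulus_protocol(amplitude = 5e4, duration = 2,
                            predicate = function(pt) rep(TRUE, nrow(pt)))
  res <- solve_monodomain(w, w$structure, p, stim, 30, sample_interval = 1)
  amp_norm <- 5e4 / (p$chi * p$C_m * 100)
  cell <- run_cell(duration = 30, dt = 0.01,
                   stim = function(t) if (t < 2) amp_norm else 0)
  Vcell <- cell$V[match(res$times, cell$t)]
  spread <- apply(res$voltage, 2, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6) # all nodes identical
  expect_lt(max(abs(res$voltage[1, ] - Vcell)) / diff(range(Vcell)), 1e-3)
})

test_that("activation pattern is invariant under rigid rotation", {
  w <- wedge_fixture(8, 8, 8, 1)
  p <- monodomain_params()
  stim <- stimulus_protocol(predicate = function(pt) pt[, 1] < 0.08)
  res <- solve_monodomain(w, w$structure, p, stim, 35)

  Rm <- rot_about(c(1, 1, 1) / sqrt(3), 0.7)
  wr <- w
  wr$nodes <- w$nodes %*% t(Rm)
  sr <- w$structure
  sr$f <- w$structure$f %*% t(Rm)
  sr$s <- w$structure$s %*% t(Rm)
  sr$n_vec <- w$structure$n_vec %*% t(Rm)
  e1r <- as.numeric(Rm %*% c(1, 0, 0))
  stim_r <- stimulus_protocol(
    predicate = function(pt) as.numeric(pt %*% e1r) < 0.08)
  res_r <- solve_monodomain(wr, sr, p, stim_r, 35)
  rng <- diff(range(res$activation))
  rms <- sqrt(mean((res$activation - res_r$activation)^2))
  expect_lt(rms / rng, 0.01)
})

test_that("halving the diffusion step barely changes activation times", {
  w <- wedge_fixture(8, 8, 8, 1)
  stim <- stimulus_protocol(predicate = function(pt) pt[, 1] < 0.08)
  p1 <- monodomain_params(dt_pde = 0.1)
  p2 <- monodomain_params(dt_pde = 0.05)
  a1 <- solve_monodomain(w, w$structure, p1, stim, 35)$activation
  a2 <- solve_monodomain(w, w$structure, p2, stim, 35)$activation
  expect_lt(max(abs(a1 - a2)) / diff(range(a2)), 0.02)
})

test_that("apical stimulation activates the whole ventricle base-ward", {
  ep_mesh <- build_lv_mesh(rat_geo$post_p, divisions = c(3, 16, 8))
  sf <- build_structure_field(ep_mesh, fibre = fibre_model(70, 1))
  res <- solve_monodomain(ep_mesh, sf, monodomain_params(),
                          stimulus_protocol(), 60)
  expect_true(all(!is.na(res$activation)))
  epi_nodes <- unique(as.vector(ep_mesh$surfaces$epicardium))
  phi <- atan2(ep_mesh$nodes[epi_nodes, 2], ep_mesh$nodes[epi_nodes, 1])
  mer <- epi_nodes[abs(phi) < 0.25]
  rho <- cor(ep_mesh$nodes[mer, 3], res$activation[mer], method = "spearman")
  expect_gt(rho, 0.95)
})
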