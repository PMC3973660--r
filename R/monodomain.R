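# Monodomain reaction-diffusion solver on linear tetrahedra.
#
# chi C_m dV/dt = div(sigma grad V) - chi I_ion + I_stim, with the
# anisotropic conductivity sigma built from the per-element fibre frame.
# Time integration uses Godunov operator splitting: the reaction (cell
# model) is advanced node-wise with explicit substeps at dt_ode (lumped
# mass), the diffusion with an implicit Euler step at dt_pde (consistent
# mass); the constant system matrix is factorized once with a sparse
# Cholesky decomposition.

#' Tissue-level electrophysiology parameters
#'
#' @param C_m membrane capacitance (uF/cm^2), default 1.
#' @param chi surface-to-volume ratio (1/cm), default 1400 (rodent
#'   myocyte range).
#' @param sigma_f,sigma_s,sigma_n conductivities along the fibre, sheet
#'   and sheet-normal directions (mS/cm).  Defaults reproduce a fibre
#'   conduction velocity of 0.06 cm/ms with a fibre:cross-fibre ratio of 2
#'   on the packaged wedge calibration (see
#'   [calibrate_conductivities()]).
#' @param dt_ode,dt_pde reaction and diffusion time steps (ms);
#'   `dt_ode <= dt_pde` is required.
#' @return Object of class `monodomain_params`.
#' @export
monodomain_params <- function(C_m = 1, chi = 1400,
                              sigma_f = 2.15, sigma_s = 2.15 / 4,
                              sigma_n = 2.15 / 4,
                              dt_ode = 0.01, dt_pde = 0.1) {
  vals <- c(C_m, chi, sigma_f, sigma_s, sigma_n, dt_ode, dt_pde)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    .stopf("all monodomain parameters must be positive")
  }
  if (dt_ode > dt_pde + 1e-12) .stopf("dt_ode must not exceed dt_pde")
  structure(list(C_m = C_m, chi = chi, sigma_f = sigma_f, sigma_s = sigma_s,
                 sigma_n = sigma_n, dt_ode = dt_ode, dt_pde = dt_pde),
            class = "monodomain_params")
}

#' Anisotropic conductivity tensor of one element
#'
#' sigma = sigma_f f f' + sigma_s s s' + sigma_n n n'; symmetric positive
#' definite with eigenvalues (sigma_f, sigma_s, sigma_n).
#'
#' @param f,s,n orthonormal frame vectors (unit, mutually orthogonal to
#'   1e-8).
#' @param params a [monodomain_params()].
#' @return 3 x 3 conductivity matrix.
#' @export
conductivity_tensor <- function(f, s, n, params) {
  G <- rbind(f, s, n)
  if (max(abs(G %*% t(G) - diag(3))) > 1e-8) {
    .stopf("frame (f, s, n) is not orthonormal")
  }
  params$sigma_f * tcrossprod(f) + params$sigma_s * tcrossprod(s) +
    params$sigma_n * tcrossprod(n)
}

#' Stimulus protocol
#'
#' @param apical_fraction fraction of the long-axis length above the apex
#'   that receives the stimulus (default 0.15, the lower 15 percent of the
#'   ventricle).  Ignored when `predicate` is given.
#' @param amplitude volumetric current density (uA/cm^3), default 5e4.
#' @param duration stimulus duration (ms), default 2.
#' @param start onset time (ms), default 0.
#' @param predicate optional `function(coords)` returning a logical mask
#'   of stimulated nodes (rows of the node coordinate matrix); used for
#'   wedge/planar protocols.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(apical_fraction = 0.15, amplitude = 5e4,
                              duration = 2, start = 0, predicate = NULL) {
  if (duration <= 0) .stopf("stimulus duration must be > 0")
  structure(list(apical_fraction = apical_fraction, amplitude = amplitude,
                 duration = duration, start = start, predicate = predicate),
            class = "stimulus_protocol")
}

.stim_nodes <- function(mesh, stim) {
  if (!is.null(stim$predicate)) {
    which(stim$predicate(mesh$nodes))
  } else {
    z <- mesh$nodes[, 3]
    L <- -min(z)
    which(z <= min(z) + stim$apical_fraction * L)
  }
}

# vectorized element gradients and volumes for linear tets
.tet_gradients <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  d2 <- nodes[elems[, 2], , drop = FALSE] - p1
  d3 <- nodes[elems[, 3], , drop = FALSE] - p1
  d4 <- nodes[elems[, 4], , drop = FALSE] - p1
  # inverse of J^T (rows d2,d3,d4) via cofactors
  det <- d2[, 1] * (d3[, 2] * d4[, 3] - d3[, 3] * d4[, 2]) -
    d2[, 2] * (d3[, 1] * d4[, 3] - d3[, 3] * d4[, 1]) +
    d2[, 3] * (d3[, 1] * d4[, 2] - d3[, 2] * d4[, 1])
  vol <- det / 6
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  # gradients of barycentric functions 2..4 (rows of inv(J), J = [d2;d3;d4])
  g2 <- cross(d3, d4) / det
  g3 <- cross(d4, d2) / det
  g4 <- cross(d2, d3) / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = vol)
}

# assemble conductivity-weighted stiffness and consistent mass matrices
.assemble_ep <- function(mesh, structure, params) {
  elems <- mesh$elems[, 1:4, drop = FALSE]
  gr <- .tet_gradients(mesh$nodes, elems)
  vol <- abs(gr$vol)
  ne <- nrow(elems)
  f <- structure$f; s <- structure$s; nv <- structure$n_vec
  # sigma as per-element symmetric tensors (6 unique entries)
  sig <- function(i, j) {
    params$sigma_f * f[, i] * f[, j] + params$sigma_s * s[, i] * s[, j] +
      params$sigma_n * nv[, i] * nv[, j]
  }
  s11 <- sig(1, 1); s22 <- sig(2, 2); s33 <- sig(3, 3)
  s12 <- sig(1, 2); s13 <- sig(1, 3); s23 <- sig(2, 3)
  sgrad <- function(g) cbind(
    s11 * g[, 1] + s12 * g[, 2] + s13 * g[, 3],
    s12 * g[, 1] + s22 * g[, 2] + s23 * g[, 3],
    s13 * g[, 1] + s23 * g[, 2] + s33 * g[, 3]
  )
  sg <- lapply(gr$g, sgrad)
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- elems[, a]
    jj[[k]] <- elems[, b]
    xx[[k]] <- vol * rowSums(sg[[a]] * gr$g[[b]])
  }
  K <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(nrow(mesh$nodes), nrow(mesh$nodes))
  )
  mm <- vol / 20
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    xx[[k]] <- if (a == b) 2 * mm else mm
  }
  M <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(nrow(mesh$nodes), nrow(mesh$nodes))
  )
  list(K = K, M = M)
}

#' Solve the monodomain equations
#'
#' @param mesh linear-tetrahedra `lv_mesh`.
#' @param structure a `structure_field` for the same mesh.
#' @param params a [monodomain_params()].
#' @param stim a [stimulus_protocol()].
#' @param duration simulated time (ms).
#' @param model cell model (default [cell_model_ms()]).
#' @param sample_interval voltage sampling interval (ms, default 1).
#' @param activation_threshold voltage whose first upward crossing defines
#'   the activation time (mV, default -20; crossings are located by linear
#'   interpolation between diffusion steps).
#' @return Object of class `activation_result`: per-node activation times
#'   (NA where unactivated, with a warning), sampled voltage matrix
#'   (nodes x samples), sample times and the mesh.
#' @export
solve_monodomain <- function(mesh, structure, params, stim, duration,
                             model = cell_model_ms(), sample_interval = 1,
                             activation_threshold = -20) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(params, "monodomain_params"))
  if (mesh$order != 1L) .stopf("the monodomain solver requires a linear mesh")
  if (nrow(structure$f) != nrow(mesh$elems)) {
    .stopf("structure field does not match the mesh")
  }
  n <- nrow(mesh$nodes)
  sys <- .assemble_ep(mesh, structure, params)
  cc <- params$chi * params$C_m
  A <- cc * sys$M + params$dt_pde * sys$K
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  Ms <- cc * sys$M

  st <- cell_state(model, n)
  stim_idx <- .stim_nodes(mesh, stim)
  if (!length(stim_idx)) .stopf("stimulus region contains no nodes")
  # normalized stimulus: dV/dt = I / (chi C_m) mV/ms, divided by amplitude A
  stim_norm <- stim$amplitude / (cc * model$A)

  nstep <- as.integer(ceiling(duration / params$dt_pde))
  nsub <- max(1L, as.integer(round(params$dt_pde / params$dt_ode)))
  dt_sub <- params$dt_pde / nsub
  every <- max(1L, as.integer(round(sample_interval / params$dt_pde)))

  t_act <- rep(NA_real_, n)
  Vprev <- cell_voltage(st)
  samples <- list(Vprev)
  sample_t <- 0
  Ivec <- numeric(n)
  for (k in seq_len(nstep)) {
    t0 <- (k - 1L) * params$dt_pde
    # reaction substeps (nodal, lumped)
    for (j in seq_len(nsub)) {
      tj <- t0 + (j - 1L) * dt_sub
      Ivec[] <- 0
      if (tj >= stim$start && tj < stim$start + stim$duration) {
        Ivec[stim_idx] <- stim_norm
      }
      st <- step_cell(st, Ivec, dt_sub)
    }
    # implicit diffusion step on the voltage, mapped back to v
    V <- cell_voltage(st)
    V <- as.numeric(Matrix::solve(ch, Ms %*% V))
    st$state$v <- (V - model$V_rest) / model$A
    tnew <- k * params$dt_pde
    cross <- is.na(t_act) & Vprev < activation_threshold & V >= activation_threshold
    if (any(cross)) {
      frac <- (activation_threshold - Vprev[cross]) / (V[cross] - Vprev[cross])
      t_act[cross] <- t0 + frac * params$dt_pde
    }
    Vprev <- V
    if (k %% every == 0L) {
      samples[[length(samples) + 1L]] <- V
      sample_t <- c(sample_t, tnew)
    }
  }
  if (anyNA(t_act) && stim$amplitude > 0) {
    .warnf("%d node(s) did not activate within %g ms", sum(is.na(t_act)), duration)
  }
  structure(
    list(activation = t_act, voltage = do.call(cbind, samples),
         times = sample_t, mesh = mesh, params = params, stim = stim,
         threshold = activation_threshold),
    class = "activation_result"
  )
}

#' @export
print.activation_result <- function(x, ...) {
  act <- x$activation[!is.na(x$activation)]
  cat(sprintf(
    "Activation result: %d/%d nodes activated%s\n",
    length(act), length(x$activation),
    if (length(act)) sprintf(", t_act in [%.2f, %.2f] ms", min(act), max(act)) else ""
  ))
  invisible(x)
}

#' Conduction velocity from a planar-wave activation map
#'
#' Fits activation time against distance along `axis` over the central
#' `window` of the domain and returns the inverse slope.
#'
#' @param result an `activation_result` from a planar (wedge) setup.
#' @param axis propagation direction (unit 3-vector).
#' @param window fraction interval of the projected extent used for the
#'   fit (default c(0.25, 0.75), excluding boundary effects).
#' @return Conduction velocity (cm/ms); fit R^2 in attribute `"r2"`.
#' @export
measure_conduction_velocity <- function(result, axis = c(1, 0, 0),
                                        window = c(0.25, 0.75)) {
  stopifnot(inherits(result, "activation_result"))
  axis <- .unit3(axis)
  sproj <- as.numeric(result$mesh$nodes %*% axis)
  rng <- range(sproj)
  lo <- rng[1] + window[1] * diff(rng)
  hi <- rng[1] + window[2] * diff(rng)
  sel <- sproj >= lo & sproj <= hi & !is.na(result$activation)
  if (sum(sel) < 10L) .stopf("too few activated nodes in the fit window")
  fit <- stats::lm(result$activation[sel] ~ sproj[sel])
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0) {
    .stopf("activation is not monotone along the requested axis")
  }
  r2 <- summary(fit)$r.squared
  structure(1 / slope, r2 = r2)
}

#' Calibrate conductivities against a target conduction velocity
#'
#' Runs planar-wave simulations on a cubic wedge with straight fibres along
#' the x axis, rescaling the fibre conductivity by the square of the
#' velocity mismatch (conduction velocity scales with the square root of
#' conductivity) until the fibre-direction velocity is within `tol` of
#' `target_cv_f`.  Cross-fibre conductivities are then set to
#' `sigma_f / target_ratio^2`.
#'
#' @param target_cv_f target fibre conduction velocity (cm/ms),
#'   default 0.06.
#' @param target_ratio target fibre:cross-fibre velocity ratio, default 2.
#' @param params starting [monodomain_params()].
#' @param wedge_divisions per-axis cell count of the calibration wedge
#'   (default 10).
#' @param wedge_edge wedge edge length (cm, default 1).
#' @param tol relative velocity tolerance (default 0.01).
#' @param max_iter maximum wedge runs (default 10; an error reports the
#'   iteration trace if exceeded).
#' @param model cell model used in the wedge runs.
#' @return Calibrated `monodomain_params`; number of wedge runs in
#'   attribute `"runs"`.
#' @export
calibrate_conductivities <- function(target_cv_f = 0.06, target_ratio = 2,
                                     params = monodomain_params(),
                                     wedge_divisions = 10, wedge_edge = 1,
                                     tol = 0.01, max_iter = 10,
                                     model = cell_model_ms()) {
  if (target_cv_f <= 0 || target_ratio <= 0) .stopf("targets must be > 0")
  mesh <- wedge_fixture(wedge_divisions, wedge_divisions, wedge_divisions,
                        wedge_edge)
  struct <- mesh$structure
  h1 <- wedge_edge / (wedge_divisions - 1)
  stim <- stimulus_protocol(
    amplitude = 5e4, duration = 2,
    predicate = function(p) p[, 1] <= 1e-9 + h1 * 0.5
  )
  duration <- wedge_edge / target_cv_f * 2 + 10
  sigma_f <- params$sigma_f
  trace <- data.frame(iter = integer(), sigma_f = numeric(), cv = numeric())
  for (it in seq_len(max_iter)) {
    p <- monodomain_params(params$C_m, params$chi, sigma_f,
                           sigma_f / target_ratio^2, sigma_f / target_ratio^2,
                           params$dt_ode, params$dt_pde)
    res <- solve_monodomain(mesh, struct, p, stim, duration,
                            model = model, sample_interval = duration)
    cv <- as.numeric(measure_conduction_velocity(res, c(1, 0, 0)))
    trace <- rbind(trace, data.frame(iter = it, sigma_f = sigma_f, cv = cv))
    if (abs(cv - target_cv_f) <= tol * target_cv_f) {
      out <- p
      attr(out, "runs") <- it
      attr(out, "trace") <- trace
      return(out)
    }
    sigma_f <- sigma_f * (target_cv_f / cv)^2
  }
  .stopf("conductivity calibration did not converge in %d runs; trace: %s",
         max_iter, paste(sprintf("%.4g->%.4g", trace$sigma_f, trace$cv),
                         collapse = "; "))
}
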