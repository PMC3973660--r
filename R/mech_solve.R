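# Quasi-static finite-elasticity solves: Newton iteration on the
# total-Lagrangian residual assembled in C++, with elimination of
# Dirichlet constraints, an aggregate penalty on the in-plane rigid modes
# left free by the long-axis-only base constraint, and automatic
# load-step halving on divergence.

#' Mechanical boundary specification
#'
#' Base nodes (reference z = 0) are fixed in the long-axis direction and
#' free to move in the short-axis plane.  The two in-plane rigid-body
#' translations and the rotation about the long axis left free by this
#' constraint are removed by penalizing the aggregate rigid modes of the
#' base ring (net in-plane translation and net rotation); the penalty
#' exerts no force on radial dilation or any other deformation of the
#' ring.  `pressure` is the endocardial cavity pressure magnitude (kPa),
#' applied inward along the deformed surface normal (follower load).
#'
#' @param pressure endocardial pressure (kPa, >= 0).
#' @param rigid_penalty stiffness (kPa cm) of the aggregate rigid-mode
#'   penalty (default 10).
#' @return Object of class `boundary_spec`.
#' @export
boundary_spec <- function(pressure = 0, rigid_penalty = 10) {
  if (!.is_scalar_num(pressure) || !is.finite(pressure)) {
    .stopf("pressure must be finite")
  }
  structure(list(pressure = pressure, rigid_penalty = rigid_penalty),
            class = "boundary_spec")
}

# base-node constraint pattern of a mesh: z dofs fixed; unit-norm aggregate
# in-plane rigid modes (translation x, translation y, rotation about z) of
# the base ring, penalized rather than sprung so ring dilation stays free
.base_constraints <- function(mesh) {
  scale <- max(abs(mesh$nodes))
  base_nodes <- which(abs(mesh$nodes[, 3]) < 1e-9 * scale)
  if (!length(base_nodes)) .stopf("no base nodes found (z = 0 plane)")
  n3 <- 3L * nrow(mesh$nodes)
  a1 <- numeric(n3); a2 <- numeric(n3); a3 <- numeric(n3)
  a1[3L * base_nodes - 2L] <- 1
  a2[3L * base_nodes - 1L] <- 1
  a3[3L * base_nodes - 2L] <- -mesh$nodes[base_nodes, 2]
  a3[3L * base_nodes - 1L] <- mesh$nodes[base_nodes, 1]
  agg <- cbind(a1 / sqrt(sum(a1^2)), a2 / sqrt(sum(a2^2)),
               a3 / sqrt(sum(a3^2)))
  list(
    fixed = 3L * base_nodes,
    fixed_vals = rep(0, length(base_nodes)),
    agg = agg
  )
}

# one Newton solve at a fixed load state.  dirichlet: list(dofs, vals);
# agg: columns of unit-norm aggregate rigid modes penalized with k_rigid.
# Returns ok flag, displacement, residual and iteration count.
.newton_solve <- function(mesh, structure, law, pressure, Ta, dirichlet,
                          agg, k_rigid, u0 = NULL, tol_rel = 1e-8,
                          max_iter = 25L) {
  n <- nrow(mesh$nodes)
  elems0 <- mesh$elems - 1L
  pfaces0 <- if (pressure != 0) mesh$surfaces$endocardium - 1L else
    matrix(integer(), 0L, 6L)
  storage.mode(pfaces0) <- "integer"
  fsn <- cbind(structure$f, structure$s, structure$n_vec)
  u <- if (is.null(u0)) numeric(3L * n) else as.numeric(t(u0))
  u[dirichlet$dofs] <- dirichlet$vals
  disp <- matrix(u, n, 3L, byrow = TRUE)
  free <- setdiff(seq_len(3L * n), dirichlet$dofs)
  agg_s <- if (!is.null(agg) && k_rigid > 0) {
    Matrix::Matrix(agg, sparse = TRUE)
  } else {
    NULL
  }
  res0 <- NULL
  for (iter in seq_len(max_iter)) {
    # cheap residual-only assembly first: skips the tangent on the final
    # (converged) iteration
    sys <- mech_system(mesh$nodes, elems0, disp, fsn, law$C0, law$b,
                       law$kappa, Ta, pfaces0, pressure, FALSE)
    if (!sys$ok) {
      return(list(ok = FALSE, reason = "element inversion", minJ = sys$minJ))
    }
    R <- sys$res
    if (!is.null(agg_s)) {
      R <- R + k_rigid * as.numeric(agg_s %*% (Matrix::crossprod(agg_s, u)))
    }
    resnorm <- sqrt(sum(R[free]^2))
    if (is.null(res0)) res0 <- max(resnorm, 1e-12)
    if (resnorm <= max(1e-10, tol_rel * res0)) {
      return(list(ok = TRUE, disp = disp, residual = R, iterations = iter - 1L))
    }
    sys <- mech_system(mesh$nodes, elems0, disp, fsn, law$C0, law$b,
                       law$kappa, Ta, pfaces0, pressure, TRUE)
    K <- Matrix::sparseMatrix(i = sys$Ki, j = sys$Kj, x = sys$Kx,
                              dims = c(3L * n, 3L * n))
    if (!is.null(agg_s)) {
      K <- K + k_rigid * Matrix::tcrossprod(agg_s)
    }
    Kf <- K[free, free, drop = FALSE]
    # the tangent is symmetric up to the (small) follower-pressure term:
    # factor the symmetrized tangent with a sparse Cholesky when positive
    # definite, falling back to an unsymmetric sparse LU otherwise
    du <- tryCatch({
      ch <- suppressWarnings(Matrix::Cholesky(
        Matrix::forceSymmetric((Kf + Matrix::t(Kf)) / 2), LDL = FALSE
      ))
      as.numeric(Matrix::solve(ch, -R[free]))
    }, error = function(e) NULL)
    if (is.null(du)) {
      du <- tryCatch(
        as.numeric(Matrix::solve(Kf, -R[free])),
        error = function(e) NULL
      )
    }
    if (is.null(du) || any(!is.finite(du))) {
      return(list(ok = FALSE, reason = "linear solve failure"))
    }
    u[free] <- u[free] + du
    disp <- matrix(u, n, 3L, byrow = TRUE)
  }
  list(ok = FALSE, reason = sprintf("no convergence in %d iterations", max_iter))
}

# incremental solve from a previous displacement towards a target load,
# with automatic halving of the load increment on divergence
.solve_loadpath <- function(mesh, structure, law, pressure, Ta, dirichlet,
                            agg, k_rigid, u0 = NULL,
                            pressure0 = 0, Ta0 = NULL, dirichlet_vals0 = NULL,
                            tol_rel = 1e-8, max_halvings = 6L) {
  Ta <- rep_len(Ta, nrow(mesh$elems))
  if (is.null(Ta0)) Ta0 <- numeric(nrow(mesh$elems))
  if (is.null(dirichlet_vals0)) dirichlet_vals0 <- numeric(length(dirichlet$vals))
  lam0 <- 0
  step <- 1
  u <- u0
  halvings <- 0L
  last <- NULL
  while (lam0 < 1 - 1e-12) {
    lam <- min(1, lam0 + step)
    dl <- dirichlet
    dl$vals <- dirichlet_vals0 + lam * (dirichlet$vals - dirichlet_vals0)
    sol <- .newton_solve(
      mesh, structure, law,
      pressure0 + lam * (pressure - pressure0),
      Ta0 + lam * (Ta - Ta0),
      dl, agg, k_rigid, u0 = u, tol_rel = tol_rel
    )
    if (sol$ok) {
      lam0 <- lam
      u <- sol$disp
      last <- sol
    } else {
      step <- step / 2
      halvings <- halvings + 1L
      if (halvings > max_halvings) {
        .stopf(
          "mechanics solve diverged (%s); last converged load fraction %.3f",
          sol$reason, lam0
        )
      }
    }
  }
  last$load_halvings <- halvings
  last
}

#' Quasi-static finite-elasticity solve on the LV mesh
#'
#' Newton solution of the momentum balance Div(F S) = 0 (inertia and
#' gravity neglected) on a quadratic mesh with the exponential material
#' law, an optional active fibre tension field and the follower
#' endocardial pressure of `boundary`.  Diverging load steps are halved
#' automatically.
#'
#' @param mesh quadratic (order 2) `lv_mesh`.
#' @param structure `structure_field` on the same mesh.
#' @param law a [material_law()].
#' @param boundary a [boundary_spec()].
#' @param Ta active fibre tension (kPa): scalar or per-element vector.
#' @param u0 optional initial displacement (nodes x 3 warm start).
#' @param tol_rel relative residual tolerance (default 1e-8).
#' @return Object of class `mech_state`: displacement, per-element
#'   centroid deformation gradient `F` (ne x 9), Jacobian `J`, reaction
#'   residual, the deformed mesh and solver diagnostics.
#' @export
solve_quasistatic <- function(mesh, structure, law,
                              boundary = boundary_spec(), Ta = 0,
                              u0 = NULL, tol_rel = 1e-8) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(law, "material_law"),
            inherits(boundary, "boundary_spec"))
  if (mesh$order != 2L) .stopf("mechanics requires a quadratic (order 2) mesh")
  if (nrow(structure$f) != nrow(mesh$elems)) {
    .stopf("structure field does not match the mesh")
  }
  if (any(Ta < 0)) .stopf("active tension must be >= 0")
  bc <- .base_constraints(mesh)
  dirichlet <- list(dofs = bc$fixed, vals = bc$fixed_vals)
  sol <- .solve_loadpath(mesh, structure, law, boundary$pressure, Ta,
                         dirichlet, bc$agg, boundary$rigid_penalty, u0 = u0,
                         tol_rel = tol_rel)
  .mech_state(mesh, sol)
}

.mech_state <- function(mesh, sol) {
  Fm <- mech_deformation(mesh$nodes, mesh$elems - 1L, sol$disp)
  J <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 6] * Fm[, 8]) -
    Fm[, 2] * (Fm[, 4] * Fm[, 9] - Fm[, 6] * Fm[, 7]) +
    Fm[, 3] * (Fm[, 4] * Fm[, 8] - Fm[, 5] * Fm[, 7])
  structure(
    list(disp = sol$disp, F = Fm, J = J, reactions = sol$residual,
         iterations = sol$iterations,
         load_halvings = sol$load_halvings %||% 0L,
         mesh_deformed = deform_mesh(mesh, mesh$nodes + sol$disp)),
    class = "mech_state"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mech_state <- function(x, ...) {
  cat(sprintf(
    "Mechanics state: max |u| = %.4g, J in [%.3f, %.3f] (median %.3f)\n",
    max(abs(x$disp)), min(x$J), max(x$J), median(x$J)
  ))
  invisible(x)
}

#' Passive inflation of the ventricle
#'
#' Expands the mesh under a constant endocardial pressure and returns the
#' deformed mesh (a post-P candidate); the converged mechanics state is
#' attached as attribute `"state"`.
#'
#' @param mesh quadratic `lv_mesh` (unloaded configuration).
#' @param structure `structure_field` on the mesh.
#' @param law a [material_law()].
#' @param pressure inflation pressure magnitude (kPa, >= 0).
#' @return Deformed `lv_mesh` with provenance `"post-P"`.
#' @export
inflate <- function(mesh, structure, law, pressure) {
  if (pressure < 0) .stopf("inflation pressure must be >= 0")
  if (pressure == 0) return(mesh)
  st <- solve_quasistatic(mesh, structure, law,
                          boundary_spec(pressure = pressure))
  out <- deform_mesh(mesh, mesh$nodes + st$disp, provenance = "post-P")
  attr(out, "state") <- st
  out
}

#' Estimate the unloaded (pre-P) geometry by uniform scaling
#'
#' Iteratively shrinks the reference mesh by a uniform scale factor s and
#' inflates the shrunk mesh under `pressure` until the inflated cavity
#' volume matches the reference cavity volume within `tol` (bisection on
#' the volume mismatch).
#'
#' @param reference quadratic `lv_mesh` (measured / reference state).
#' @param structure `structure_field` on the reference mesh (directions
#'   are scale-invariant, so the same field applies to the shrunk mesh).
#' @param law a [material_law()].
#' @param pressure preload pressure (kPa, default 0.5).
#' @param tol relative cavity-volume tolerance (default 0.02).
#' @param max_iter maximum bisection iterations (default 15).
#' @return List with the converged scale `s`, meshes `pre_p` and
#'   `post_p`, and the relative volume mismatch `volume_error`.
#' @export
estimate_unloaded <- function(reference, structure, law, pressure = 0.5,
                              tol = 0.02, max_iter = 15L) {
  stopifnot(inherits(reference, "lv_mesh"))
  V_ref <- mesh_volumes(reference)[["cavity"]]
  if (pressure == 0) {
    return(list(s = 1, pre_p = reference, post_p = reference,
                volume_error = 0))
  }
  mismatch <- function(s) {
    pre <- scale_mesh(reference, s)
    post <- inflate(pre, structure, law, pressure)
    (mesh_volumes(post)[["cavity"]] - V_ref) / V_ref
  }
  f_hi <- mismatch(1)
  if (abs(f_hi) < tol) {
    pre <- reference
    post <- inflate(pre, structure, law, pressure)
    return(list(s = 1, pre_p = pre, post_p = post, volume_error = f_hi))
  }
  if (f_hi < 0) .stopf("inflation at s = 1 did not expand the cavity; cannot bracket")
  s_lo <- 0.9
  f_lo <- mismatch(s_lo)
  tries <- 0L
  while (f_lo > 0 && tries < 4L) {
    s_lo <- s_lo - 0.1
    f_lo <- mismatch(s_lo)
    tries <- tries + 1L
  }
  if (f_lo > 0) {
    .stopf("failed to bracket the unloaded scale (mismatch %.3f at s = %.2f)",
           f_lo, s_lo)
  }
  s_hi <- 1
  s_best <- NA_real_
  f_best <- Inf
  for (it in seq_len(max_iter)) {
    s <- (s_lo + s_hi) / 2
    f <- mismatch(s)
    if (abs(f) < abs(f_best)) {
      f_best <- f
      s_best <- s
    }
    if (abs(f) < tol) break
    if (f > 0) s_hi <- s else s_lo <- s
  }
  if (abs(f_best) >= tol) {
    .stopf("unloaded-geometry estimation did not reach %.0f%% in %d iterations (best %.3f)",
           100 * tol, max_iter, f_best)
  }
  pre <- scale_mesh(reference, s_best)
  pre$provenance <- "pre-P"
  post <- inflate(pre, structure, law, pressure)
  list(s = s_best, pre_p = pre, post_p = post, volume_error = f_best)
}
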