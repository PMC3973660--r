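# Global deformation metrics (ejection fraction, wall thickening,
# base-to-apex shortening) and local cylindrical Lagrangian strains with
# regional (thirds) averaging.  All metrics operate on a
# `simulation_result`, whether produced by the coupled simulation or by
# the analytic-motion generator.

# index of the sample closest to time t (error when outside range)
.sample_index <- function(result, t) {
  if (t < min(result$times) - 1e-9 || t > max(result$times) + 1e-9) {
    .stopf("time %g ms is outside the sampled range [%g, %g]",
           t, min(result$times), max(result$times))
  }
  which.min(abs(result$times - t))
}

# deformed lv_mesh at a sample
.mesh_at <- function(result, idx) {
  deform_mesh(result$mesh, result$nodes[[idx]],
              provenance = sprintf("t=%g", result$times[idx]))
}

#' Ejection fraction between two sampled states
#'
#' EF = (V(t0) - V(t1)) / V(t0) from the cavity-volume trace; positive for
#' ejection, negative if the cavity dilates.
#'
#' @param result a `simulation_result`.
#' @param t0,t1 start and end times (ms, default first and last samples).
#' @return Ejection fraction (dimensionless).
#' @export
ejection_fraction <- function(result, t0 = NULL, t1 = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(t0)) t0 <- min(result$times)
  if (is.null(t1)) t1 <- max(result$times)
  if (t0 >= t1) .stopf("require t0 < t1")
  V0 <- result$volumes[.sample_index(result, t0)]
  V1 <- result$volumes[.sample_index(result, t1)]
  if (!is.finite(V0) || V0 <= 0) .stopf("non-positive cavity volume at t0")
  (V0 - V1) / V0
}

#' Wall thickening between two sampled states
#'
#' Difference of [wall_thickness()] measured on the deformed meshes at t1
#' and t0 in the configured short-axis slice.
#'
#' @inheritParams ejection_fraction
#' @param slice_fraction slice position as a fraction of the long axis
#'   from the base (default 0.5, midventricular).
#' @param n_rays number of rays (default 4).
#' @return Thickness change (length units; positive = thickening).
#' @export
wall_thickening <- function(result, slice_fraction = 0.5, t0 = NULL,
                            t1 = NULL, n_rays = 4) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(t0)) t0 <- min(result$times)
  if (is.null(t1)) t1 <- max(result$times)
  i0 <- .sample_index(result, t0)
  i1 <- .sample_index(result, t1)
  wt0 <- wall_thickness(.mesh_at(result, i0), slice_fraction, n_rays)
  wt1 <- wall_thickness(.mesh_at(result, i1), slice_fraction, n_rays)
  as.numeric(wt1) - as.numeric(wt0)
}

#' Base-to-apex shortening between two sampled states
#'
#' Change in apico-basal length, tracked through the epicardial apex node
#' of the reference mesh (the base plane is fixed in the long-axis
#' direction): negative values mean shortening, positive elongation.
#'
#' @inheritParams ejection_fraction
#' @return Length change (length units; negative = shortening).
#' @export
base_apex_shortening <- function(result, t0 = NULL, t1 = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(t0)) t0 <- min(result$times)
  if (is.null(t1)) t1 <- max(result$times)
  i0 <- .sample_index(result, t0)
  i1 <- .sample_index(result, t1)
  epi_nodes <- unique(as.vector(result$mesh$surfaces$epicardium))
  apex <- epi_nodes[which.min(result$mesh$nodes[epi_nodes, 3])]
  L0 <- -result$nodes[[i0]][apex, 3]
  L1 <- -result$nodes[[i1]][apex, 3]
  L1 - L0
}

# cylindrical basis (c, r, l as columns) at reference element centroids;
# elements whose centroid sits on the long axis are flagged
.cyl_basis <- function(mesh) {
  el <- mesh$elems[, 1:4, drop = FALSE]
  cx <- rowMeans(matrix(mesh$nodes[el, 1], ncol = 4L))
  cy <- rowMeans(matrix(mesh$nodes[el, 2], ncol = 4L))
  rad <- sqrt(cx^2 + cy^2)
  ok <- rad > 1e-8 * max(abs(mesh$nodes))
  er <- cbind(cx / rad, cy / rad, 0)
  ec <- cbind(-er[, 2], er[, 1], 0) # long axis (z) x radial
  list(er = er, ec = ec, ok = ok)
}

#' Cylindrical Lagrangian strain components over a sampled trajectory
#'
#' For every sample and element, computes E = (F'F - I)/2 from the
#' centroid deformation gradient and rotates it into the local cylindrical
#' basis of the reference centroid (circumferential, radial,
#' longitudinal); returns the circumferential normal strain E_cc and the
#' shear strains E_cl (circumferential-longitudinal, torsion) and E_cr
#' (circumferential-radial, transmural twist).  Elements whose centroid
#' lies on the long axis are excluded and reported.
#'
#' @param result a `simulation_result` carrying per-sample deformation
#'   gradients.
#' @return Object of class `strain_series`: matrices `E_cc`, `E_cl`,
#'   `E_cr` (elements x samples), sample `times`, long-axis `thirds`
#'   labels ("basal"/"mid"/"apical") and the logical mask `included`.
#' @export
cylindrical_strains <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  mesh <- result$mesh
  bas <- .cyl_basis(mesh)
  if (any(!bas$ok)) {
    message(sprintf("cylindrical_strains: %d element(s) on the long axis excluded",
                    sum(!bas$ok)))
  }
  nt <- length(result$times)
  ne <- nrow(mesh$elems)
  E_cc <- E_cl <- E_cr <- matrix(NA_real_, ne, nt)
  ec <- bas$ec; er <- bas$er
  for (k in seq_len(nt)) {
    Fm <- result$F[[k]]
    # C = F^T F, E = (C - I)/2, components via basis contractions
    # column layout of Fm: F11 F12 F13 F21 F22 F23 F31 F32 F33
    Fc <- cbind(
      Fm[, 1] * ec[, 1] + Fm[, 2] * ec[, 2] + Fm[, 3] * ec[, 3],
      Fm[, 4] * ec[, 1] + Fm[, 5] * ec[, 2] + Fm[, 6] * ec[, 3],
      Fm[, 7] * ec[, 1] + Fm[, 8] * ec[, 2] + Fm[, 9] * ec[, 3]
    )
    Fr <- cbind(
      Fm[, 1] * er[, 1] + Fm[, 2] * er[, 2] + Fm[, 3] * er[, 3],
      Fm[, 4] * er[, 1] + Fm[, 5] * er[, 2] + Fm[, 6] * er[, 3],
      Fm[, 7] * er[, 1] + Fm[, 8] * er[, 2] + Fm[, 9] * er[, 3]
    )
    Fl <- cbind(Fm[, 3], Fm[, 6], Fm[, 9]) # F e_l, e_l = z
    E_cc[, k] <- (rowSums(Fc * Fc) - 1) / 2
    E_cl[, k] <- rowSums(Fc * Fl) / 2
    E_cr[, k] <- rowSums(Fc * Fr) / 2
  }
  E_cc[!bas$ok, ] <- NA_real_
  E_cl[!bas$ok, ] <- NA_real_
  E_cr[!bas$ok, ] <- NA_real_

  el <- mesh$elems[, 1:4, drop = FALSE]
  cz <- rowMeans(matrix(mesh$nodes[el, 3], ncol = 4L))
  L <- -min(mesh$nodes[, 3])
  frac <- -cz / L
  thirds <- cut(frac, c(-Inf, 1 / 3, 2 / 3, Inf),
                labels = c("basal", "mid", "apical"))
  structure(
    list(E_cc = E_cc, E_cl = E_cl, E_cr = E_cr, times = result$times,
         thirds = thirds, included = bas$ok),
    class = "strain_series"
  )
}

#' Regional (thirds) average strain traces
#'
#' Unweighted mean of each strain component over the basal, mid and apical
#' thirds at every sample.  With `subtract_residual = TRUE` the value at
#' the first sample is subtracted component-wise, so traces start at zero
#' (removing, e.g., the residual strain left by a passive pre-inflation).
#'
#' @param series a [cylindrical_strains()] result.
#' @param subtract_residual subtract the first-sample value (default
#'   FALSE).
#' @return Data frame with columns `time`, `region`, `component`,
#'   `value`.
#' @export
regional_average <- function(series, subtract_residual = FALSE) {
  stopifnot(inherits(series, "strain_series"))
  comps <- list(E_cc = series$E_cc, E_cl = series$E_cl, E_cr = series$E_cr)
  out <- list()
  for (reg in c("basal", "mid", "apical")) {
    sel <- series$thirds == reg & series$included
    if (!any(sel)) .stopf("empty region '%s'", reg)
    for (cn in names(comps)) {
      tr <- colMeans(comps[[cn]][sel, , drop = FALSE], na.rm = TRUE)
      if (subtract_residual) tr <- tr - tr[1]
      out[[length(out) + 1L]] <- data.frame(
        time = series$times, region = reg, component = cn, value = tr
      )
    }
  }
  do.call(rbind, out)
}

#' Global metrics summary of a simulation result
#'
#' @param result a `simulation_result`.
#' @param t0,t1 comparison times (default first and last samples).
#' @param slice_fraction midventricular slice position for wall
#'   thickening.
#' @return Data frame with EF, WT and SBA.
#' @export
global_metrics <- function(result, t0 = NULL, t1 = NULL,
                           slice_fraction = 0.5) {
  data.frame(
    EF = ejection_fraction(result, t0, t1),
    WT = wall_thickening(result, slice_fraction, t0, t1),
    SBA = base_apex_shortening(result, t0, t1)
  )
}
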