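# Fibre and sheet architecture: rule-based transmural angle models, the
# rotation construction that turns material axes into fibre/sheet frames,
# the 16-region partition, and regional fitting of the helix-angle rule to
# axial fibre-direction observations.

#' Rule-based fibre model specification
#'
#' A Streeter-type transmural helix-angle rule with transmural rotation `R`
#' (degrees, the magnitude reached at both surfaces) and shape exponent `n`.
#' The model name encodes the two parameters, e.g. `"Sn1R70"`.
#'
#' @param R transmural rotation in degrees, in (0, 90].
#' @param n transmural exponent, > 0 (1 = linear, 3 = cubic profile).
#' @return Object of class `fibre_model`.
#' @export
fibre_model <- function(R, n) {
  if (!.is_scalar_num(R) || R <= 0 || R > 90) .stopf("R must lie in (0, 90]")
  if (!.is_scalar_num(n) || n <= 0) .stopf("n must be > 0")
  structure(
    list(kind = "rule_based", R = R, n = n,
         name = sprintf("Sn%gR%g", n, R)),
    class = "fibre_model"
  )
}

#' @export
print.fibre_model <- function(x, ...) {
  cat(sprintf("Rule-based fibre model %s (R = %g deg, n = %g)\n",
              x$name, x$R, x$n))
  invisible(x)
}

#' The family of rule-based fibre models
#'
#' Crossing the transmural rotation values `R_values` with the exponents
#' `n_values` yields the 4 x 4 = 16 global fibre models compared in the
#' study design.
#'
#' @param R_values transmural rotations in degrees (default 50, 60, 70, 80).
#' @param n_values exponents (default 0.5, 1, 2, 3).
#' @return Named list of [fibre_model()] objects.
#' @export
rule_based_models <- function(R_values = c(50, 60, 70, 80),
                              n_values = c(0.5, 1, 2, 3)) {
  out <- list()
  for (R in R_values) for (n in n_values) {
    m <- fibre_model(R, n)
    out[[m$name]] <- m
  }
  out
}

#' Transmural helix angle
#'
#' theta(w) = R * sgn(1 - 2 w) * |1 - 2 w|^n, in degrees: +R at the
#' endocardium (w = 0), 0 at midwall, -R at the epicardium (w = 1),
#' odd-symmetric about midwall; linear across the wall for n = 1, cubic
#' for n = 3.
#'
#' @param w normalized transmural depth(s) in [0, 1].
#' @param R transmural rotation (degrees).
#' @param n transmural exponent (> 0).
#' @return Helix angle(s) in degrees.
#' @examples
#' helix_angle(c(0, 0.5, 1), R = 70, n = 1)
#' @export
helix_angle <- function(w, R, n) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    .stopf("transmural depth w must lie in [0, 1]")
  }
  x <- 1 - 2 * w
  R * sign(x) * abs(x)^n
}

#' Sheet-angle model specification
#'
#' Linear model: beta(w) interpolates linearly from `beta_endo` to
#' `beta_epi`.  Bimodal model: a sigmoidal step between the same endpoints,
#' beta(w) = beta_endo + (beta_epi - beta_endo) / (1 + exp(-k (w - 1/2))),
#' emulating two sheet populations of opposing orientation with a smooth
#' but distinct transmural transition.
#'
#' @param kind `"linear"` or `"bimodal"`.
#' @param beta_endo,beta_epi endpoint angles in degrees, |beta| <= 90
#'   (defaults +45 / -45).
#' @param k sigmoid steepness for the bimodal model (default 30, giving a
#'   10-90 percent transition over about 0.15 of the wall).
#' @return Object of class `sheet_model`.
#' @export
sheet_model <- function(kind = c("linear", "bimodal"),
                        beta_endo = 45, beta_epi = -45, k = 30) {
  kind <- match.arg(kind)
  if (abs(beta_endo) > 90 || abs(beta_epi) > 90) {
    .stopf("sheet endpoint angles must satisfy |beta| <= 90")
  }
  if (!.is_scalar_num(k) || k <= 0) .stopf("k must be > 0")
  structure(list(kind = kind, beta_endo = beta_endo, beta_epi = beta_epi,
                 k = k),
            class = "sheet_model")
}

#' Transmural sheet angle
#'
#' @param w normalized transmural depth(s) in [0, 1].
#' @param spec a [sheet_model()].
#' @return Sheet angle(s) in degrees.
#' @export
sheet_angle <- function(w, spec) {
  stopifnot(inherits(spec, "sheet_model"))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    .stopf("transmural depth w must lie in [0, 1]")
  }
  d <- spec$beta_epi - spec$beta_endo
  if (spec$kind == "linear") {
    spec$beta_endo + d * w
  } else {
    spec$beta_endo + d / (1 + exp(-spec$k * (w - 0.5)))
  }
}

#' Regional fibre model (per-region helix-angle parameters)
#'
#' A fibre model with one (R, n) pair for each of the 16 regions of the
#' ventricular partition, typically the product of
#' [fit_regional_fibre_model()].
#'
#' @param R,n numeric vectors of length 16 (region order 1..16).
#' @param residual optional per-region mean angular error of a fit
#'   (degrees).
#' @param boundary optional logical vector flagging regions whose fit ended
#'   on the search boundary.
#' @return Object of class `regional_fibre_model`.
#' @export
regional_fibre_model <- function(R, n, residual = rep(NA_real_, 16),
                                 boundary = rep(FALSE, 16)) {
  if (length(R) != 16L || length(n) != 16L) {
    .stopf("a regional fibre model needs exactly 16 (R, n) pairs")
  }
  if (any(R <= 0) || any(R > 90) || any(n <= 0)) {
    .stopf("require R in (0, 90] and n > 0 for every region")
  }
  structure(list(kind = "regional", R = as.numeric(R), n = as.numeric(n),
                 residual = residual, boundary = boundary,
                 name = "regional"),
            class = "regional_fibre_model")
}

#' @export
print.regional_fibre_model <- function(x, ...) {
  cat("Regional fibre model (16 regions)\n")
  print(data.frame(region = 1:16, R = x$R, n = x$n,
                   residual_deg = x$residual, boundary = x$boundary))
  invisible(x)
}

#' Partition an LV mesh into 16 regions
#'
#' Deterministic adaptation of the 17-segment classification with the apex
#' cap dropped: the basal and middle thirds of the long axis are each split
#' into 6 azimuthal sectors of 60 degrees and the apical third into 4
#' sectors of 90 degrees.  Sector 1 starts at the +x meridian; regions are
#' numbered 1-6 (basal), 7-12 (mid), 13-16 (apical).
#'
#' @param mesh an `lv_mesh`.
#' @return Integer vector of region labels (1..16), one per element.
#' @export
partition_regions <- function(mesh) {
  stopifnot(inherits(mesh, "lv_mesh"))
  el <- mesh$elems[, 1:4, drop = FALSE]
  cx <- rowMeans(matrix(mesh$nodes[el, 1], ncol = 4L))
  cy <- rowMeans(matrix(mesh$nodes[el, 2], ncol = 4L))
  cz <- rowMeans(matrix(mesh$nodes[el, 3], ncol = 4L))
  L <- -min(mesh$nodes[, 3])
  frac <- -cz / L # 0 at base, 1 at apex
  az <- atan2(cy, cx) %% (2 * pi)
  lab <- integer(length(cx))
  basal <- frac < 1 / 3
  mid <- frac >= 1 / 3 & frac < 2 / 3
  apical <- frac >= 2 / 3
  lab[basal] <- 1L + as.integer(floor(az[basal] / (pi / 3)) %% 6)
  lab[mid] <- 7L + as.integer(floor(az[mid] / (pi / 3)) %% 6)
  lab[apical] <- 13L + as.integer(floor(az[apical] / (pi / 2)) %% 4)
  lab
}

#' Build the per-element fibre/sheet/sheet-normal structure field
#'
#' Two successive rotations applied to the material axes of every element:
#' first the circumferential and longitudinal axes are rotated about the
#' radial axis by the helix angle theta, giving the fibre direction
#' f = cos(theta) c + sin(theta) l; then the radial axis and the rotated
#' longitudinal axis are rotated about f by the sheet angle beta, giving
#' the sheet direction s; the sheet normal is n = f x s, so every (f, s, n)
#' triple is orthonormal and right-handed (det +1).
#'
#' @param mesh an `lv_mesh`.
#' @param frame a [material_axes()] frame (computed from `mesh` if `NULL`).
#' @param w per-element transmural depths (computed from `mesh` if `NULL`).
#' @param fibre a [fibre_model()] or [regional_fibre_model()].
#' @param sheet a [sheet_model()].
#' @param regions per-element region labels, required for a regional fibre
#'   model (computed by [partition_regions()] if `NULL`).
#' @return Object of class `structure_field`: ne x 3 matrices `f`, `s`,
#'   `n_vec`, plus per-element `theta` and `beta` (degrees) and provenance.
#' @export
build_structure_field <- function(mesh, frame = NULL, w = NULL, fibre,
                                  sheet = sheet_model("linear"),
                                  regions = NULL) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(sheet, "sheet_model"))
  if (is.null(frame)) frame <- material_axes(mesh)
  if (is.null(w)) w <- transmural_depth(mesh)
  ne <- nrow(frame$r)
  if (length(w) != ne) .stopf("depth field length does not match element count")

  if (inherits(fibre, "regional_fibre_model")) {
    if (is.null(regions)) regions <- partition_regions(mesh)
    if (length(regions) != ne || any(is.na(regions)) ||
        any(regions < 1L | regions > 16L)) {
      .stopf("missing or invalid region label for a regional fibre model")
    }
    theta <- fibre$R[regions] * sign(1 - 2 * w) * abs(1 - 2 * w)^(fibre$n[regions])
  } else if (inherits(fibre, "fibre_model")) {
    theta <- helix_angle(w, fibre$R, fibre$n)
  } else {
    .stopf("fibre must be a fibre_model or regional_fibre_model")
  }
  beta <- sheet_angle(w, sheet)

  th <- .deg2rad(theta)
  be <- .deg2rad(beta)
  f <- cos(th) * frame$c + sin(th) * frame$l
  lp <- -sin(th) * frame$c + cos(th) * frame$l
  # rotation about f maps r -> s; note f x r = -lp for this construction
  s <- cos(be) * frame$r - sin(be) * lp
  n_vec <- cbind(
    f[, 2] * s[, 3] - f[, 3] * s[, 2],
    f[, 3] * s[, 1] - f[, 1] * s[, 3],
    f[, 1] * s[, 2] - f[, 2] * s[, 1]
  )
  structure(
    list(f = f, s = s, n_vec = n_vec, theta = theta, beta = beta,
         fibre = fibre, sheet = sheet,
         regions = if (inherits(fibre, "regional_fibre_model")) regions else NULL),
    class = "structure_field"
  )
}

#' @export
print.structure_field <- function(x, ...) {
  cat(sprintf("Structure field: %d elements, fibre model %s, %s sheets\n",
              nrow(x$f), x$fibre$name, x$sheet$kind))
  invisible(x)
}

#' Angular difference between two axial directions
#'
#' Sign-free angle arccos(|u . v|) in degrees, in [0, 90]; appropriate for
#' axial data such as diffusion-tensor primary eigenvectors, for which v
#' and -v are the same observation.
#'
#' @param u,v unit 3-vectors, or n x 3 matrices of unit rows.
#' @return Angle(s) in degrees.
#' @export
angular_difference <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, 1L)
  if (is.null(dim(v))) v <- matrix(v, 1L)
  nu <- .rownorm(u); nv <- .rownorm(v)
  if (any(nu < 1e-12) || any(nv < 1e-12)) .stopf("zero vector in angular_difference")
  d <- abs(rowSums(u * v)) / (nu * nv)
  out <- .rad2deg(acos(pmin(d, 1)))
  if (length(out) == 1L) out[[1L]] else out
}

# mean sign-free angular error of the helix rule (R, n) against
# observations, given per-element depth and the projections of the
# observation on the circumferential (a) and longitudinal (b) axes
.rule_fit_error <- function(R, n, w, a, b) {
  th <- .deg2rad(R * sign(1 - 2 * w) * abs(1 - 2 * w)^n)
  d <- pmin(abs(cos(th) * a + sin(th) * b), 1)
  mean(.rad2deg(acos(d)))
}

#' Fit the helix-angle rule per region to fibre-direction observations
#'
#' For each of the 16 regions, finds the (R, n) pair minimizing the mean
#' sign-free angular difference between the rule-predicted fibre direction
#' and the observed axial directions.  The search is a deterministic coarse
#' grid (R from 30 to 90 degrees in 1-degree steps, n log-spaced over
#' [0.25, 4]) followed by bounded local refinement; ties on the grid are
#' broken towards smaller n, then smaller R.  Fits ending on the search
#' boundary are flagged.
#'
#' @param mesh an `lv_mesh`.
#' @param frame material axes (default computed from `mesh`).
#' @param w per-element depths (default computed from `mesh`).
#' @param observations a `fibre_observations` object (see
#'   [synth_fibre_observations()]) or an ne x 3 matrix of axial unit
#'   vectors.
#' @param regions per-element region labels (default
#'   [partition_regions()]).
#' @param R_grid,n_grid search grids (defaults as above).
#' @param min_per_region minimum observations required per region
#'   (default 10).
#' @return A [regional_fibre_model()] with per-region residuals.
#' @export
fit_regional_fibre_model <- function(mesh, frame = NULL, w = NULL,
                                     observations, regions = NULL,
                                     R_grid = seq(30, 90, by = 1),
                                     n_grid = exp(seq(log(0.25), log(4),
                                                      length.out = 13)),
                                     min_per_region = 10L) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(frame)) frame <- material_axes(mesh)
  if (is.null(w)) w <- transmural_depth(mesh)
  if (is.null(regions)) regions <- partition_regions(mesh)
  obs <- if (inherits(observations, "fibre_observations")) {
    observations$vectors
  } else {
    observations
  }
  ne <- nrow(frame$r)
  if (!is.matrix(obs) || nrow(obs) != ne || ncol(obs) != 3L) {
    .stopf("observations must provide one unit 3-vector per element")
  }
  nn <- .rownorm(obs)
  if (any(abs(nn - 1) > 1e-8)) .stopf("observations must be unit vectors (tol 1e-8)")

  a <- rowSums(obs * frame$c)
  b <- rowSums(obs * frame$l)

  empty <- setdiff(1:16, unique(regions))
  if (length(empty)) {
    .stopf("empty region(s): %s", paste(empty, collapse = ", "))
  }
  small <- which(tabulate(regions, 16L) < min_per_region)
  if (length(small)) {
    .stopf("region(s) with fewer than %d observations: %s",
           min_per_region, paste(small, collapse = ", "))
  }

  Rf <- nf <- resf <- numeric(16)
  bnd <- logical(16)
  for (reg in 1:16) {
    idx <- which(regions == reg)
    wr <- w[idx]; ar <- a[idx]; br <- b[idx]
    best <- Inf; bR <- NA; bn <- NA
    for (n in n_grid) { # n-major order implements the tie-break
      # vectorize the error over the R grid
      base <- sign(1 - 2 * wr) * abs(1 - 2 * wr)^n
      for (R in R_grid) {
        th <- .deg2rad(R * base)
        err <- mean(.rad2deg(acos(pmin(abs(cos(th) * ar + sin(th) * br), 1))))
        if (err < best - 1e-12) {
          best <- err; bR <- R; bn <- n
        }
      }
    }
    ref <- stats::optim(
      c(bR, bn),
      function(p) .rule_fit_error(p[1], p[2], wr, ar, br),
      method = "L-BFGS-B",
      lower = c(min(R_grid), min(n_grid)),
      upper = c(max(R_grid), max(n_grid))
    )
    Rf[reg] <- ref$par[1]; nf[reg] <- ref$par[2]; resf[reg] <- ref$value
    bnd[reg] <- any(abs(ref$par - c(min(R_grid), min(n_grid))) < 1e-6) ||
      any(abs(ref$par - c(max(R_grid), max(n_grid))) < 1e-6)
  }
  regional_fibre_model(Rf, nf, residual = resf, boundary = bnd)
}
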