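# Passive and active myocardial material behaviour.
#
# Passive response: exponential strain-energy function of the
# Green-Lagrange strain expressed in the fibre coordinate system,
# W = (C0/2) (exp(Q) - 1),
# Q = b_ff E_ff^2 + b_ss E_ss^2 + b_nn E_nn^2
#     + b_fs (E_fs^2 + E_sf^2) + b_fn (E_fn^2 + E_nf^2)
#     + b_sn (E_sn^2 + E_ns^2),
# plus a convex volumetric penalty kappa (J ln J - J + 1) that vanishes at
# J = 1 and controls the level of compressibility.  Active response: a
# second Piola-Kirchhoff stress T_a f0 (x) f0 along the reference fibre
# direction only.

#' Exponential orthotropic/transversely isotropic material law
#'
#' @param C0 stress scale (kPa), default 0.88.
#' @param b exponents in the order (b_ff, b_ss, b_nn, b_fs, b_fn, b_sn).
#' @param kappa volumetric penalty modulus (kPa), default 100, chosen so a
#'   pressurized contraction stays nearly incompressible (median element
#'   Jacobian within a few percent of 1).
#' @param symmetry `"orthotropic"` or `"transverse_isotropic"`; transverse
#'   isotropy requires b_ss = b_nn and b_fs = b_fn (and is exactly
#'   insensitive to rotations of the sheet plane when additionally
#'   b_sn = b_ss, as in the default parameter set).
#' @return Object of class `material_law`.
#' @seealso [law_orthotropic()], [law_transverse_isotropic()]
#' @export
material_law <- function(C0 = 0.88, b, kappa = 100,
                         symmetry = c("orthotropic", "transverse_isotropic")) {
  symmetry <- match.arg(symmetry)
  b <- as.numeric(b)
  if (length(b) != 6L) .stopf("b must be (b_ff, b_ss, b_nn, b_fs, b_fn, b_sn)")
  if (any(!is.finite(c(C0, b, kappa))) || C0 <= 0 || kappa <= 0 || any(b <= 0)) {
    .stopf("all material parameters must be positive")
  }
  if (symmetry == "transverse_isotropic" &&
      (abs(b[2] - b[3]) > 1e-12 || abs(b[4] - b[5]) > 1e-12)) {
    .stopf("transverse isotropy requires b_ss = b_nn and b_fs = b_fn")
  }
  names(b) <- c("b_ff", "b_ss", "b_nn", "b_fs", "b_fn", "b_sn")
  structure(list(C0 = C0, b = b, kappa = kappa, symmetry = symmetry),
            class = "material_law")
}

#' Orthotropic stiffness set
#'
#' Exponents (b_ff, b_ss, b_nn, b_fs, b_fn, b_sn) =
#' (6.0, 7.0, 3.0, 12.0, 3.0, 3.0).
#' @param C0,kappa see [material_law()].
#' @return A `material_law`.
#' @export
law_orthotropic <- function(C0 = 0.88, kappa = 100) {
  material_law(C0, c(6, 7, 3, 12, 3, 3), kappa, "orthotropic")
}

#' Transversely isotropic stiffness set
#'
#' Obtained from the orthotropic set by averaging over the sheet and
#' sheet-normal directions: (6.0, 4.3, 4.3, 7.5, 7.5, 4.3).
#' @param C0,kappa see [material_law()].
#' @return A `material_law`.
#' @export
law_transverse_isotropic <- function(C0 = 0.88, kappa = 100) {
  material_law(C0, c(6, 4.3, 4.3, 7.5, 7.5, 4.3), kappa,
               "transverse_isotropic")
}

#' @export
print.material_law <- function(x, ...) {
  cat(sprintf("Exponential material law (%s): C0 = %g kPa, kappa = %g kPa\n",
              x$symmetry, x$C0, x$kappa))
  cat("  b:", paste(sprintf("%s=%g", names(x$b), x$b), collapse = " "), "\n")
  invisible(x)
}

# symmetric exponent matrix used in Q
.b_matrix <- function(law) {
  b <- law$b
  matrix(c(b[1], b[4], b[5],
           b[4], b[2], b[6],
           b[5], b[6], b[3]), 3L, 3L)
}

#' Green-Lagrange strain from a deformation gradient
#'
#' E = (F' F - I) / 2.
#'
#' @param F 3 x 3 deformation gradient with det F > 0.
#' @return Symmetric 3 x 3 strain tensor.
#' @export
green_strain <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  if (det(F) <= 0) .stopf("deformation gradient must have positive determinant")
  (crossprod(F) - diag(3)) / 2
}

# J implied by a Green strain (J = sqrt(det(2E + I)))
.jacobian_from_strain <- function(E) {
  d <- det(2 * E + diag(3))
  if (d <= 0) .stopf("strain state implies a non-positive Jacobian")
  sqrt(d)
}

#' Strain-energy density of the exponential law
#'
#' @param E Green-Lagrange strain expressed in the fibre coordinate system
#'   (f, s, n).
#' @param law a [material_law()].
#' @param J deformation Jacobian; if `NULL`, computed from `E` as
#'   sqrt(det(2E + I)).
#' @return Energy density (kPa).
#' @export
strain_energy <- function(E, law, J = NULL) {
  stopifnot(inherits(law, "material_law"))
  E <- as.matrix(E)
  if (is.null(J)) J <- .jacobian_from_strain(E)
  if (J <= 0) .stopf("J must be > 0")
  Q <- sum(.b_matrix(law) * E * E)
  law$C0 / 2 * (exp(Q) - 1) + law$kappa * (J * log(J) - J + 1)
}

#' Passive second Piola-Kirchhoff stress
#'
#' Analytic derivative of the strain energy with respect to the
#' Green-Lagrange strain, including the volumetric term:
#' S_p = C0 exp(Q) (B o E) + kappa J ln(J) C^{-1}, with C = 2E + I and
#' B the exponent matrix (o is the elementwise product).
#'
#' @inheritParams strain_energy
#' @return Symmetric 3 x 3 stress tensor (kPa) in fibre coordinates.
#' @export
passive_stress <- function(E, law, J = NULL) {
  stopifnot(inherits(law, "material_law"))
  E <- as.matrix(E)
  Cten <- 2 * E + diag(3)
  d <- det(Cten)
  if (d <= 0) .stopf("strain state implies a non-positive Jacobian")
  if (is.null(J)) J <- sqrt(d)
  if (J <= 0) .stopf("J must be > 0")
  Q <- sum(.b_matrix(law) * E * E)
  S <- law$C0 * exp(Q) * (.b_matrix(law) * E) +
    law$kappa * J * log(J) * solve(Cten)
  (S + t(S)) / 2
}

#' Active second Piola-Kirchhoff stress
#'
#' S_a = T_a f0 (x) f0: active tension along the reference fibre direction
#' only.
#'
#' @param T_a active tension (kPa, >= 0).
#' @param f reference fibre direction (unit 3-vector).
#' @return Symmetric 3 x 3 stress tensor.
#' @export
active_stress <- function(T_a, f) {
  if (!.is_scalar_num(T_a) || T_a < 0) .stopf("active tension must be >= 0")
  f <- .unit3(as.numeric(f))
  T_a * tcrossprod(f)
}
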