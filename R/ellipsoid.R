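#' Truncated-ellipsoid left-ventricle geometry specification
#'
#' Describes a thick-walled half (or more) ellipsoid of revolutionized
#' cross-section: the wall is bounded by two confocal-like ellipsoid surfaces
#' (epicardial outside, endocardial inside) sharing a common centre and axis
#' orientation, truncated by a basal plane perpendicular to the long axis.
#' The long axis is the third coordinate axis; the base plane sits at z = 0
#' and the apex points towards negative z.
#'
#' @param epi_semiaxes numeric length-3, epicardial semi-axes (a, b, c) in
#'   length units (cm by default). `c` is the long (apico-basal) semi-axis.
#' @param endo_semiaxes numeric length-3, endocardial semi-axes; each must be
#'   strictly smaller than the corresponding epicardial one.
#' @param truncation_fraction position of the base plane along the long axis
#'   as a fraction of the epicardial long semi-axis; 0 (default) truncates at
#'   the equator, values in (0, 0.5) truncate above it.
#' @param unit length unit label carried through outputs (default `"cm"`).
#'
#' @return An object of class `ellipsoid_spec`.
#' @examples
#' spec <- ellipsoid_spec(c(0.34, 0.48, 0.95), c(0.16, 0.27, 0.79))
#' @export
ellipsoid_spec <- function(epi_semiaxes, endo_semiaxes,
                           truncation_fraction = 0, unit = "cm") {
  epi <- as.numeric(epi_semiaxes)
  endo <- as.numeric(endo_semiaxes)
  if (length(epi) != 3L || length(endo) != 3L) {
    .stopf("semi-axes must be numeric vectors of length 3")
  }
  if (any(!is.finite(epi)) || any(!is.finite(endo))) {
    .stopf("semi-axes must be finite")
  }
  if (any(endo <= 0) || any(epi <= 0)) .stopf("all semi-axes must be > 0")
  if (any(epi <= endo)) {
    .stopf(
      "degenerate spec: each epicardial semi-axis must exceed the endocardial one (epi = %s, endo = %s)",
      paste(epi, collapse = ", "), paste(endo, collapse = ", ")
    )
  }
  if (!.is_scalar_num(truncation_fraction) ||
      truncation_fraction < 0 || truncation_fraction >= 0.5) {
    .stopf("truncation_fraction must lie in [0, 0.5)")
  }
  structure(
    list(
      epi = epi, endo = endo,
      truncation_fraction = truncation_fraction,
      unit = unit
    ),
    class = "ellipsoid_spec"
  )
}

#' @export
print.ellipsoid_spec <- function(x, ...) {
  cat("Truncated-ellipsoid LV specification\n")
  cat(sprintf("  epicardial semi-axes : %s %s\n",
              paste(format(x$epi), collapse = " "), x$unit))
  cat(sprintf("  endocardial semi-axes: %s %s\n",
              paste(format(x$endo), collapse = " "), x$unit))
  cat(sprintf("  base plane at %.3f of long axis above equator\n",
              x$truncation_fraction))
  invisible(x)
}

#' Rat left-ventricle mesh dimensions (pre-P and post-P states)
#'
#' Semi-axis sets for the unloaded (pre-P) and passively pressurized
#' (post-P) states of the idealized rat left ventricle, in cm:
#' pre-P epicardial (0.34, 0.48, 0.95) / endocardial (0.16, 0.27, 0.79),
#' post-P epicardial (0.40, 0.48, 0.99) / endocardial (0.26, 0.30, 0.84).
#' The pre-P endocardial half-ellipsoid volume (2/3) pi a b c is about
#' 0.0715 cm^3 and the equatorial wall thickness along the first axis is
#' 0.34 - 0.16 = 0.18 cm.
#'
#' @return Named list with `ellipsoid_spec` entries `pre_p` and `post_p`.
#' @export
rat_lv_geometry <- function() {
  list(
    pre_p = ellipsoid_spec(c(0.34, 0.48, 0.95), c(0.16, 0.27, 0.79)),
    post_p = ellipsoid_spec(c(0.40, 0.48, 0.99), c(0.26, 0.30, 0.84))
  )
}

# closed-form cavity volume of the truncated endocardial half-ellipsoid:
# volume of the ellipsoid cap below the base plane z = z_pl (z_pl >= 0
# measured from the centre, apex side).  For z_pl = 0 this is the
# half-ellipsoid (2/3) pi a b c.
.ellipsoid_cap_volume <- function(a, b, c, z_pl) {
  # V = pi a b (c - h + ...) for the region z < z_pl of (x/a)^2+(y/b)^2+(z/c)^2<1
  # with z from -c to z_pl: V = pi a b [ z - z^3/(3 c^2) ]_{-c}^{z_pl}
  f <- function(z) z - z^3 / (3 * c^2)
  pi * a * b * (f(z_pl) - f(-c))
}

#' Closed-form cavity and tissue volumes of a truncated-ellipsoid spec
#'
#' Analytic volumes of the region enclosed by the endocardial surface plus
#' base cap (cavity) and of the shell between the two surfaces (tissue).
#' Used as the refinement-independent oracle for mesh-based integration.
#'
#' @param spec an [ellipsoid_spec()].
#' @return Named numeric vector with elements `cavity` and `tissue`.
#' @export
ellipsoid_volumes <- function(spec) {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  z_pl <- spec$truncation_fraction * spec$epi[3]
  cav <- .ellipsoid_cap_volume(spec$endo[1], spec$endo[2], spec$endo[3], z_pl)
  outer <- .ellipsoid_cap_volume(spec$epi[1], spec$epi[2], spec$epi[3], z_pl)
  c(cavity = cav, tissue = outer - cav)
}
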