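# Synthetic inputs: every quantity the pipeline consumes can be generated
# here, so the full analysis runs without any external dataset.  Three
# generators are provided: DT-MRI-like axial fibre observations with a
# known ground truth, analytic motion fields whose deformation metrics
# have closed forms, and a structured cubic wedge used by the conduction
# calibration.

#' Configuration for synthetic fibre-direction observations
#'
#' @param truth a [fibre_model()] or [regional_fibre_model()] providing the
#'   ground-truth helix-angle field.
#' @param noise_sd angular noise standard deviation in degrees (default 15,
#'   the dispersion reported for diffusion-tensor-derived rat fibre
#'   fields).
#' @param seed integer RNG seed (reproducibility contract).
#' @return Object of class `synthetic_fibre_config`.
#' @export
synthetic_fibre_config <- function(truth = fibre_model(70, 1), noise_sd = 15,
                                   seed = 1L) {
  if (!.is_scalar_num(noise_sd) || noise_sd < 0) .stopf("noise_sd must be >= 0")
  structure(list(truth = truth, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_fibre_config")
}

#' Generate DT-MRI-like fibre-direction observations
#'
#' Emulates the primary eigenvector of a diffusion tensor: for each element
#' the ground-truth fibre direction is rotated by an angle drawn from a
#' wrapped normal distribution (sd `noise_sd` degrees) about a uniformly
#' random axis perpendicular to the fibre, and the sign of the resulting
#' axial vector is flipped at random.  Fully reproducible from the seed.
#'
#' @param mesh an `lv_mesh`.
#' @param frame material axes (default computed from `mesh`).
#' @param w per-element depths (default computed from `mesh`).
#' @param config a [synthetic_fibre_config()].
#' @return Object of class `fibre_observations`: matrix `vectors`
#'   (ne x 3 axial unit vectors), the truth field and the config.
#' @export
synth_fibre_observations <- function(mesh, frame = NULL, w = NULL,
                                     config = synthetic_fibre_config()) {
  stopifnot(inherits(mesh, "lv_mesh"),
            inherits(config, "synthetic_fibre_config"))
  if (is.null(frame)) frame <- material_axes(mesh)
  if (is.null(w)) w <- transmural_depth(mesh)
  truth <- build_structure_field(mesh, frame, w, fibre = config$truth)
  f <- truth$f
  ne <- nrow(f)
  set.seed(config$seed)
  # wrapped-normal rotation angle about a random perpendicular axis
  alpha <- .deg2rad((rnorm(ne, 0, config$noise_sd) + 180) %% 360 - 180)
  phi <- runif(ne, 0, 2 * pi)
  # perpendicular basis per element
  ref <- matrix(rep(c(0, 0, 1), each = ne), ne, 3L)
  swap <- abs(f[, 3]) > 0.9
  ref[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3L)
  p1 <- .rowunit(cbind(
    ref[, 2] * f[, 3] - ref[, 3] * f[, 2],
    ref[, 3] * f[, 1] - ref[, 1] * f[, 3],
    ref[, 1] * f[, 2] - ref[, 2] * f[, 1]
  ))
  p2 <- cbind(
    f[, 2] * p1[, 3] - f[, 3] * p1[, 2],
    f[, 3] * p1[, 1] - f[, 1] * p1[, 3],
    f[, 1] * p1[, 2] - f[, 2] * p1[, 1]
  )
  axis <- cos(phi) * p1 + sin(phi) * p2
  axf <- cbind(
    axis[, 2] * f[, 3] - axis[, 3] * f[, 2],
    axis[, 3] * f[, 1] - axis[, 1] * f[, 3],
    axis[, 1] * f[, 2] - axis[, 2] * f[, 1]
  )
  obs <- cos(alpha) * f + sin(alpha) * axf
  flip <- sample(c(-1, 1), ne, replace = TRUE)
  obs <- obs * flip
  structure(list(vectors = obs, truth = truth, config = config),
            class = "fibre_observations")
}

#' @export
print.fibre_observations <- function(x, ...) {
  cat(sprintf(
    "Synthetic fibre observations: %d axial vectors (truth %s, noise sd %g deg, seed %d)\n",
    nrow(x$vectors), x$truth$fibre$name, x$config$noise_sd, x$config$seed
  ))
  invisible(x)
}

#' Analytic motion field with closed-form strains
#'
#' Composition of an in-plane radial scaling, a long-axis scaling and a
#' twist about the long axis, each ramped in time: at ramp value q the
#' in-plane factor is 1 + q (radial - 1), the long-axis factor
#' 1 + q (longitudinal - 1) and the twist rate q * torsion.  The
#' deformation gradient, cavity volume, wall thickness, apex displacement
#' and cylindrical strains all have closed forms, which makes this motion
#' the oracle for the metrics module.
#'
#' @param radial in-plane scaling factor at full ramp (> 0).
#' @param longitudinal long-axis scaling factor at full ramp (> 0).
#' @param torsion twist rate at full ramp (degrees per length unit).
#' @param ramp function(t) in [0, 1] (default linear over `t_end`).
#' @param t_end time at which the ramp reaches 1 (ms, default 100).
#' @return Object of class `analytic_motion`.
#' @export
analytic_motion <- function(radial = 1, longitudinal = 1, torsion = 0,
                            ramp = NULL, t_end = 100) {
  if (radial <= 0 || longitudinal <= 0) .stopf("scaling factors must be > 0")
  if (is.null(ramp)) ramp <- function(t) pmin(pmax(t / t_end, 0), 1)
  structure(list(radial = radial, longitudinal = longitudinal,
                 torsion = torsion, ramp = ramp),
            class = "analytic_motion")
}

# factors at time t
.motion_factors <- function(motion, t) {
  q <- motion$ramp(t)
  list(
    a = 1 + q * (motion$radial - 1),
    b = 1 + q * (motion$longitudinal - 1),
    g = .deg2rad(q * motion$torsion)
  )
}

#' Apply an analytic motion to a mesh
#'
#' @param mesh an `lv_mesh` (reference configuration).
#' @param motion an [analytic_motion()].
#' @param t time (ms).
#' @return List with the deformed `mesh` and the exact deformation
#'   gradient `F` at each element centroid (ne x 9, row-major rows
#'   F11, F12, ..., F33).
#' @export
apply_motion <- function(mesh, motion, t) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(motion, "analytic_motion"))
  fac <- .motion_factors(motion, t)
  a <- fac$a; b <- fac$b; g <- fac$g
  X <- mesh$nodes
  cz <- cos(g * X[, 3]); sz <- sin(g * X[, 3])
  newn <- cbind(
    a * (cz * X[, 1] - sz * X[, 2]),
    a * (sz * X[, 1] + cz * X[, 2]),
    b * X[, 3]
  )
  el <- mesh$elems[, 1:4, drop = FALSE]
  cen <- cbind(
    rowMeans(matrix(X[el, 1], ncol = 4L)),
    rowMeans(matrix(X[el, 2], ncol = 4L)),
    rowMeans(matrix(X[el, 3], ncol = 4L))
  )
  cc <- cos(g * cen[, 3]); ss <- sin(g * cen[, 3])
  Fm <- cbind(
    a * cc, -a * ss, a * g * (-ss * cen[, 1] - cc * cen[, 2]),
    a * ss, a * cc, a * g * (cc * cen[, 1] - ss * cen[, 2]),
    0, 0, rep(b, nrow(cen))
  )
  list(mesh = deform_mesh(mesh, newn, provenance = "analytic-motion"),
       F = Fm)
}

#' Sampled analytic-motion trajectory in simulation-result form
#'
#' Packages an analytic motion applied at a series of times into the same
#' container produced by [run_simulation()], so every metric can be
#' checked against its closed form.
#'
#' @param mesh reference `lv_mesh`.
#' @param motion an [analytic_motion()].
#' @param times sample times (ms).
#' @return A `simulation_result`.
#' @export
motion_result <- function(mesh, motion, times = seq(0, 100, by = 10)) {
  nodes <- vector("list", length(times))
  Fs <- vector("list", length(times))
  vols <- numeric(length(times))
  for (i in seq_along(times)) {
    mv <- apply_motion(mesh, motion, times[i])
    nodes[[i]] <- mv$mesh$nodes
    Fs[[i]] <- mv$F
    vols[i] <- mesh_volumes(mv$mesh)[["cavity"]]
  }
  structure(
    list(times = times, nodes = nodes, F = Fs, volumes = vols,
         pressures = rep(0, length(times)), mesh = mesh, structure = NULL,
         activation = NULL, config = list(kind = "analytic_motion",
                                          motion = motion)),
    class = "simulation_result"
  )
}

#' Structured cubic wedge fixture
#'
#' Axis-aligned box meshed with the same conformal hex-to-tet split as the
#' ventricular mesh ((nx-1)(ny-1)(nz-1) cells, six tetrahedra each), with
#' constant axis-aligned structure frames (fibre = x, sheet = y,
#' sheet-normal = z) attached as `$structure`, transmural depth x / edge,
#' and the six box faces tagged `xmin`, `xmax`, `ymin`, `ymax`, `zmin`,
#' `zmax` (stimuli are applied on `xmin`).
#'
#' @param nx,ny,nz node counts per axis (>= 2).
#' @param edge edge length of the box along x (cm); y and z use the same
#'   node spacing.
#' @param order element order (1 or 2).
#' @return An `lv_mesh` with a `$structure` field.
#' @export
wedge_fixture <- function(nx = 10, ny = 10, nz = 10, edge = 1, order = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 2L)) .stopf("node counts must be >= 2")
  h <- edge / (nx - 1)
  xs <- seq(0, edge, length.out = nx)
  ys <- seq(0, h * (ny - 1), length.out = ny)
  zs <- seq(0, h * (nz - 1), length.out = nz)
  nid <- function(i, j, k) ((k - 1L) * ny + (j - 1L)) * nx + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  cells <- expand.grid(i = 1:(nx - 1L), j = 1:(ny - 1L), k = 1:(nz - 1L))
  corner <- cbind(
    nid(cells$i, cells$j, cells$k), nid(cells$i + 1L, cells$j, cells$k),
    nid(cells$i + 1L, cells$j + 1L, cells$k), nid(cells$i, cells$j + 1L, cells$k),
    nid(cells$i, cells$j, cells$k + 1L), nid(cells$i + 1L, cells$j, cells$k + 1L),
    nid(cells$i + 1L, cells$j + 1L, cells$k + 1L), nid(cells$i, cells$j + 1L, cells$k + 1L)
  )
  elems <- do.call(rbind, lapply(seq_len(nrow(.kuhn_pattern)), function(q) {
    corner[, .kuhn_pattern[q, ], drop = FALSE]
  }))
  storage.mode(elems) <- "integer"
  vol <- .tet_signed_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- elems[flip, 3L]
    elems[flip, 3L] <- elems[flip, 4L]
    elems[flip, 4L] <- tmp
  }
  faces <- .boundary_faces(elems)
  fx <- matrix(nodes[faces, 1], ncol = 3L)
  fy <- matrix(nodes[faces, 2], ncol = 3L)
  fz <- matrix(nodes[faces, 3], ncol = 3L)
  tolr <- 1e-9 * max(edge, 1)
  surfaces <- list(
    xmin = faces[rowSums(abs(fx) < tolr) == 3L, , drop = FALSE],
    xmax = faces[rowSums(abs(fx - max(xs)) < tolr) == 3L, , drop = FALSE],
    ymin = faces[rowSums(abs(fy) < tolr) == 3L, , drop = FALSE],
    ymax = faces[rowSums(abs(fy - max(ys)) < tolr) == 3L, , drop = FALSE],
    zmin = faces[rowSums(abs(fz) < tolr) == 3L, , drop = FALSE],
    zmax = faces[rowSums(abs(fz - max(zs)) < tolr) == 3L, , drop = FALSE]
  )
  mesh <- .new_lv_mesh(nodes, elems, 1L, surfaces, nodes[, 1] / edge,
                       provenance = "wedge")
  if (order == 2L) mesh <- .make_quadratic(mesh)
  ne <- nrow(mesh$elems)
  ex <- matrix(rep(c(1, 0, 0), each = ne), ne, 3L)
  ey <- matrix(rep(c(0, 1, 0), each = ne), ne, 3L)
  ez <- matrix(rep(c(0, 0, 1), each = ne), ne, 3L)
  mesh$structure <- structure(
    list(f = ex, s = ey, n_vec = ez, theta = rep(0, ne), beta = rep(0, ne),
         fibre = list(name = "axis-aligned"), sheet = list(kind = "none")),
    class = "structure_field"
  )
  mesh
}
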