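# Structured tetrahedral meshing of the truncated-ellipsoid shell.
#
# The wall is meshed on a parametric grid (transmural depth u, longitudinal
# parameter t, azimuth phi).  Each grid cell is a hexahedron split into six
# tetrahedra along a fixed corner diagonal (Kuhn split); because the split
# pattern is translation-invariant in index space, neighbouring cells share
# face diagonals and the mesh is conformal, including across the periodic
# azimuthal seam.  The apex row of cells collapses onto per-layer pole nodes,
# which turns the Kuhn pattern into three tetrahedra per wedge.

# Kuhn 6-tet split of a hexahedron given its 8 corner ids in the order
# (000,100,110,010,001,101,111,011); all tets share the 000-111 diagonal.
.kuhn_pattern <- rbind(
  c(1L, 2L, 3L, 7L),
  c(1L, 3L, 4L, 7L),
  c(1L, 4L, 8L, 7L),
  c(1L, 8L, 5L, 7L),
  c(1L, 5L, 6L, 7L),
  c(1L, 6L, 2L, 7L)
)

# signed volumes of tets given node coords and ne x 4 connectivity
.tet_signed_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c3 <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
    b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
    b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
}

#' Per-element volumes of a tetrahedral mesh
#'
#' Volumes are computed from the corner nodes (exact for straight-edged
#' elements of either order).
#'
#' @param mesh an `lv_mesh`.
#' @return Numeric vector of element volumes.
#' @export
element_volumes <- function(mesh) {
  .tet_signed_volumes(mesh$nodes, mesh$elems[, 1:4, drop = FALSE])
}

# extract boundary faces (appearing in exactly one tet) with outward
# orientation; returns matrix nf x 3 of node ids
.boundary_faces <- function(elems) {
  # outward-oriented faces of a positively oriented tet (a,b,c,d)
  f1 <- elems[, c(2, 3, 4), drop = FALSE]
  f2 <- elems[, c(1, 4, 3), drop = FALSE]
  f3 <- elems[, c(1, 2, 4), drop = FALSE]
  f4 <- elems[, c(1, 3, 2), drop = FALSE]
  faces <- rbind(f1, f2, f3, f4)
  # order-free numeric key per face (node ids fit well below 2^17)
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  K <- max(hi) + 1
  key <- (as.numeric(lo) * K + mid) * K + hi
  ord <- order(key)
  ks <- key[ord]
  nf <- length(ks)
  single <- ks != c(-Inf, ks[-nf]) & ks != c(ks[-1], Inf)
  faces[ord[single], , drop = FALSE]
}

.new_lv_mesh <- function(nodes, elems, order, surfaces, node_depth,
                         provenance, spec = NULL, unit = "cm",
                         frames_hint = NULL) {
  structure(
    list(
      nodes = nodes, elems = elems, order = order, surfaces = surfaces,
      node_depth = node_depth, provenance = provenance, spec = spec,
      unit = unit, frames_hint = frames_hint
    ),
    class = "lv_mesh"
  )
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf(
    "LV tetrahedral mesh (%s): %d nodes, %d elements (order %d)\n",
    x$provenance, nrow(x$nodes), nrow(x$elems), x$order
  ))
  cat(sprintf(
    "  surfaces: endocardium %d, epicardium %d, base %d faces\n",
    nrow(x$surfaces$endocardium), nrow(x$surfaces$epicardium),
    nrow(x$surfaces$base)
  ))
  invisible(x)
}

# point on one ellipsoid surface; psi = 0 at the apex pole, psi_base at the
# base plane.  Coordinates already shifted so the base plane is z = 0.
.surf_point <- function(axes, psi, phi, z_shift) {
  cbind(
    axes[1] * sin(psi) * cos(phi),
    axes[2] * sin(psi) * sin(phi),
    -axes[3] * cos(psi) - z_shift
  )
}

#' Build the truncated-ellipsoid left-ventricle mesh
#'
#' Meshes the shell between the endocardial and epicardial ellipsoid
#' surfaces, cut by the base plane, with a structured conformal tetrahedral
#' grid.  Boundary faces are tagged `endocardium`, `epicardium` and `base`.
#' The normalized transmural depth of every node (0 at endocardium, 1 at
#' epicardium, linear along the local transmural ray of the construction)
#' is stored with the mesh.
#'
#' @param spec an [ellipsoid_spec()].
#' @param target_edge_length requested edge length (same unit as the spec);
#'   must be smaller than the smallest wall thickness.  Ignored if
#'   `divisions` is given.
#' @param order element order, 1 (4-node) or 2 (10-node, straight-edged
#'   midside nodes).
#' @param divisions optional integer vector `c(nr, ntheta, nz)` of layer
#'   counts across the wall, around the azimuth and from base to apex,
#'   overriding the edge-length heuristic.
#' @param provenance label stored with the mesh (default `"reference"`).
#'
#' @return An `lv_mesh` object.
#' @examples
#' mesh <- build_lv_mesh(rat_lv_geometry()$pre_p, divisions = c(2, 12, 6))
#' mesh_volumes(mesh)
#' @export
build_lv_mesh <- function(spec, target_edge_length = 0.1, order = 1,
                          divisions = NULL, provenance = "reference") {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  if (!order %in% c(1, 2)) .stopf("order must be 1 or 2")
  min_thick <- min(spec$epi - spec$endo)
  z_pl <- spec$truncation_fraction * spec$epi[3]
  if (z_pl >= spec$endo[3]) {
    .stopf("truncation plane lies above the endocardial surface")
  }
  if (is.null(divisions)) {
    if (!.is_scalar_num(target_edge_length) || target_edge_length <= 0) {
      .stopf("target_edge_length must be a positive number")
    }
    if (target_edge_length >= min_thick) {
      .stopf(
        "target_edge_length (%.3g) must be below the smallest wall thickness (%.3g); spec: epi %s / endo %s",
        target_edge_length, min_thick,
        paste(spec$epi, collapse = ","), paste(spec$endo, collapse = ",")
      )
    }
    h <- target_edge_length
    nr <- max(2L, as.integer(ceiling(mean(spec$epi - spec$endo) / h)))
    ntheta <- max(8L, as.integer(ceiling(pi * (spec$epi[1] + spec$epi[2]) / h)))
    nz <- max(4L, as.integer(ceiling(0.5 * pi * spec$epi[3] / h)))
  } else {
    divisions <- as.integer(divisions)
    if (length(divisions) != 3L || any(divisions < c(1L, 4L, 2L))) {
      .stopf("divisions must be c(nr >= 1, ntheta >= 4, nz >= 2)")
    }
    nr <- divisions[1]; ntheta <- divisions[2]; nz <- divisions[3]
  }

  psi_base_en <- acos(-z_pl / spec$endo[3])
  psi_base_ep <- acos(-z_pl / spec$epi[3])

  n_ring <- (nr + 1L) * ntheta
  n_nodes <- nz * n_ring + (nr + 1L)
  nodes <- matrix(0, n_nodes, 3L)
  depth <- numeric(n_nodes)
  ir_tag <- integer(n_nodes)
  it_tag <- integer(n_nodes)

  nid <- function(ir, it, ip) {
    # ir in 0..nr, it in 0..nz (it == nz is the pole), ip in 0..ntheta-1;
    # ir and it are scalars here, ip may be a vector
    if (it == nz) {
      rep.int(nz * n_ring + ir + 1L, length(ip))
    } else {
      it * n_ring + ir * ntheta + (ip %% ntheta) + 1L
    }
  }

  phi <- 2 * pi * (0:(ntheta - 1L)) / ntheta
  for (it in 0:(nz - 1L)) {
    tfrac <- it / nz
    psi_en <- psi_base_en * (1 - tfrac)
    psi_ep <- psi_base_ep * (1 - tfrac)
    pe <- .surf_point(spec$endo, psi_en, phi, -z_pl)
    pp <- .surf_point(spec$epi, psi_ep, phi, -z_pl)
    for (ir in 0:nr) {
      u <- ir / nr
      id <- nid(ir, it, 0:(ntheta - 1L))
      nodes[id, ] <- (1 - u) * pe + u * pp
      depth[id] <- u
      ir_tag[id] <- ir
      it_tag[id] <- it
    }
  }
  # pole nodes
  for (ir in 0:nr) {
    u <- ir / nr
    id <- nid(ir, nz, 0L)
    nodes[id, ] <- c(0, 0, -((1 - u) * spec$endo[3] + u * spec$epi[3]) + z_pl)
    depth[id] <- u
    ir_tag[id] <- ir
    it_tag[id] <- nz
  }

  # hexahedral cells -> Kuhn tets (degenerate apex cells drop to 3 tets)
  tets <- vector("list", nr * nz)
  k <- 0L
  for (it in 0:(nz - 1L)) {
    for (ir in 0:(nr - 1L)) {
      ip <- 0:(ntheta - 1L)
      corner <- cbind(
        nid(ir, it, ip), nid(ir + 1L, it, ip),
        nid(ir + 1L, it, ip + 1L), nid(ir, it, ip + 1L),
        nid(ir, it + 1L, ip), nid(ir + 1L, it + 1L, ip),
        nid(ir + 1L, it + 1L, ip + 1L), nid(ir, it + 1L, ip + 1L)
      )
      cell <- do.call(rbind, lapply(seq_len(nrow(.kuhn_pattern)), function(q) {
        corner[, .kuhn_pattern[q, ], drop = FALSE]
      }))
      # drop degenerate tets (collapsed pole cells repeat node ids)
      dup <- (cell[, 1] == cell[, 2]) | (cell[, 1] == cell[, 3]) |
        (cell[, 1] == cell[, 4]) | (cell[, 2] == cell[, 3]) |
        (cell[, 2] == cell[, 4]) | (cell[, 3] == cell[, 4])
      k <- k + 1L
      tets[[k]] <- cell[!dup, , drop = FALSE]
    }
  }
  elems <- do.call(rbind, tets[seq_len(k)])
  storage.mode(elems) <- "integer"

  vol <- .tet_signed_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- elems[flip, 3L]
    elems[flip, 3L] <- elems[flip, 4L]
    elems[flip, 4L] <- tmp
  }
  vol <- abs(vol)
  if (any(vol < 1e-300)) {
    .stopf("meshing failure: degenerate elements for spec epi %s / endo %s",
           paste(spec$epi, collapse = ","), paste(spec$endo, collapse = ","))
  }

  faces <- .boundary_faces(elems)
  face_ir_min <- matrix(ir_tag[faces], ncol = 3L)
  face_it <- matrix(it_tag[faces], ncol = 3L)
  is_endo <- rowSums(face_ir_min == 0L) == 3L
  is_epi <- rowSums(face_ir_min == nr) == 3L
  is_base <- rowSums(face_it == 0L) == 3L
  if (any(is_endo + is_epi + is_base != 1L)) {
    .stopf("internal error: boundary face with ambiguous or missing tag")
  }
  surfaces <- list(
    endocardium = faces[is_endo, , drop = FALSE],
    epicardium = faces[is_epi, , drop = FALSE],
    base = faces[is_base, , drop = FALSE]
  )

  mesh <- .new_lv_mesh(nodes, elems, 1L, surfaces, depth, provenance,
                       spec = spec, unit = spec$unit)
  mesh$divisions <- c(nr = nr, ntheta = ntheta, nz = nz)
  if (order == 2L) mesh <- .make_quadratic(mesh)
  mesh
}

# tet10 edge ordering: columns 5..10 are midside nodes of the corner edges
.tet10_edges <- rbind(
  c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L)
)

# upgrade a linear mesh to straight-edged quadratic (tet10 / tri6)
.make_quadratic <- function(mesh) {
  if (mesh$order != 1L) .stopf("mesh is already quadratic")
  elems <- mesh$elems
  ne <- nrow(elems)
  e1 <- elems[, .tet10_edges[, 1]]
  e2 <- elems[, .tet10_edges[, 2]]
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  edge_lo <- lo[uk]; edge_hi <- hi[uk]
  n0 <- nrow(mesh$nodes)
  mid_id <- n0 + match(key, key[uk])
  mid_nodes <- (mesh$nodes[edge_lo, , drop = FALSE] +
    mesh$nodes[edge_hi, , drop = FALSE]) / 2
  nodes <- rbind(mesh$nodes, mid_nodes)
  depth <- c(mesh$node_depth, (mesh$node_depth[edge_lo] +
    mesh$node_depth[edge_hi]) / 2)
  elems10 <- cbind(elems, matrix(mid_id, ne, 6L))
  storage.mode(elems10) <- "integer"

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lookup <- mid_id[uk]
  names(lookup) <- paste(edge_lo, edge_hi)
  up_tris <- function(tris) {
    if (nrow(tris) == 0L) return(matrix(integer(), 0L, 6L))
    m12 <- lookup[edge_key(tris[, 1], tris[, 2])]
    m23 <- lookup[edge_key(tris[, 2], tris[, 3])]
    m31 <- lookup[edge_key(tris[, 3], tris[, 1])]
    out <- cbind(tris, m12, m23, m31)
    storage.mode(out) <- "integer"
    dimnames(out) <- NULL
    out
  }
  surfaces <- lapply(mesh$surfaces, up_tris)
  out <- mesh
  out$nodes <- nodes
  out$elems <- elems10
  out$order <- 2L
  out$surfaces <- surfaces
  out$node_depth <- depth
  out
}

#' Cavity and tissue volume of an LV mesh
#'
#' The tissue volume is the sum of element volumes.  The cavity volume is
#' the volume enclosed by the endocardial surface closed with the flat base
#' cap, obtained by the divergence theorem (tetrahedral fan from the origin,
#' which lies in the base plane so the cap contributes nothing).
#'
#' @param mesh an `lv_mesh` with tagged surfaces.
#' @return Named numeric vector `c(cavity =, tissue =)`.
#' @export
mesh_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "lv_mesh"))
  tissue <- sum(abs(.tet_signed_volumes(mesh$nodes, mesh$elems[, 1:4, drop = FALSE])))
  endo <- mesh$surfaces$endocardium
  if (is.null(endo) || nrow(endo) == 0L) {
    return(c(cavity = NA_real_, tissue = tissue))
  }
  .check_surface_closed(mesh)
  c(cavity = .cavity_volume(mesh$nodes, endo), tissue = tissue)
}

# cavity volume from endocardial triangles (corner nodes only; origin must
# lie in the base plane)
.cavity_volume <- function(nodes, endo_tris) {
  a <- nodes[endo_tris[, 1], , drop = FALSE]
  b <- nodes[endo_tris[, 2], , drop = FALSE]
  c3 <- nodes[endo_tris[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
  abs(s)
}

# every non-shared edge of the endocardial surface must lie in the base plane
.check_surface_closed <- function(mesh) {
  tris <- mesh$surfaces$endocardium[, 1:3, drop = FALSE]
  if (nrow(tris) == 0L) .stopf("mesh has no endocardial surface")
  ed <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  open_edges <- unique(as.vector(ed[key %in% names(which(table(key) == 1L)), ]))
  if (length(open_edges)) {
    zs <- mesh$nodes[open_edges, 3]
    scale <- max(abs(mesh$nodes))
    if (any(abs(zs) > 1e-8 * scale)) {
      .stopf("open endocardial surface: rim not confined to the base plane")
    }
  }
  invisible(TRUE)
}

#' Normalized transmural depth per element
#'
#' Returns the per-element wall depth w (0 at the endocardium, 1 at the
#' epicardium), evaluated at the element centroid as the mean of the corner
#' depths.  Depth is assigned at construction as the normalized position
#' along the local transmural ray between the two surfaces and is carried
#' through scaling and deformation.  Values are clamped to [0, 1].
#'
#' @param mesh an `lv_mesh` carrying node depths.
#' @return Numeric vector, one value per element.
#' @export
transmural_depth <- function(mesh) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(mesh$node_depth)) .stopf("mesh carries no transmural depth field")
  w <- rowMeans(matrix(mesh$node_depth[mesh$elems[, 1:4]], ncol = 4L))
  n_out <- sum(w < 0 | w > 1)
  if (n_out > 0L) {
    message(sprintf("transmural_depth: clamped %d element value(s) to [0, 1]", n_out))
  }
  pmin(pmax(w, 0), 1)
}

#' Per-element material coordinate frame (radial, circumferential, longitudinal)
#'
#' The radial direction r is the normalized gradient of the transmural depth
#' field (outward).  The longitudinal direction l is the long-axis direction
#' (+z, towards the base) projected orthogonally to r; the circumferential
#' direction is c = l x r, making (r, c, l) a right-handed orthonormal
#' triple.  Near the apex, where the long axis is almost parallel to r, c is
#' taken from the azimuthal direction instead and l = r x c; the number of
#' such fallbacks is reported via `message()`.
#'
#' @param mesh an `lv_mesh`.
#' @return Object of class `material_frame`: list of ne x 3 matrices
#'   `r`, `c`, `l`.
#' @export
material_axes <- function(mesh) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(mesh$node_depth)) .stopf("mesh carries no transmural depth field")
  el <- mesh$elems[, 1:4, drop = FALSE]
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  d2 <- mesh$nodes[el[, 2], , drop = FALSE] - p1
  d3 <- mesh$nodes[el[, 3], , drop = FALSE] - p1
  d4 <- mesh$nodes[el[, 4], , drop = FALSE] - p1
  w1 <- mesh$node_depth[el[, 1]]
  dw <- cbind(mesh$node_depth[el[, 2]] - w1,
              mesh$node_depth[el[, 3]] - w1,
              mesh$node_depth[el[, 4]] - w1)
  # solve J^T grad = dw per element, J rows = (d2, d3, d4)
  ne <- nrow(el)
  grad <- matrix(0, ne, 3L)
  for (e in seq_len(ne)) {
    J <- rbind(d2[e, ], d3[e, ], d4[e, ])
    grad[e, ] <- solve(J, dw[e, ])
  }
  r <- .rowunit(grad)
  kz <- c(0, 0, 1)
  lraw <- matrix(rep(kz, each = ne), ne, 3L) - r * r[, 3]
  ln <- .rownorm(lraw)
  degen <- ln < 1e-6
  n_degen <- sum(degen)
  l <- lraw
  l[!degen, ] <- lraw[!degen, , drop = FALSE] / ln[!degen]
  cvec <- cbind(
    l[, 2] * r[, 3] - l[, 3] * r[, 2],
    l[, 3] * r[, 1] - l[, 1] * r[, 3],
    l[, 1] * r[, 2] - l[, 2] * r[, 1]
  )
  if (n_degen > 0L) {
    cent <- (p1 + (d2 + d3 + d4) / 4)
    for (e in which(degen)) {
      az <- c(-cent[e, 2], cent[e, 1], 0)
      if (.norm3(az) < 1e-12) az <- c(0, 1, 0)
      az <- az - sum(az * r[e, ]) * r[e, ]
      cvec[e, ] <- .unit3(az)
      l[e, ] <- c(
        r[e, 2] * cvec[e, 3] - r[e, 3] * cvec[e, 2],
        r[e, 3] * cvec[e, 1] - r[e, 1] * cvec[e, 3],
        r[e, 1] * cvec[e, 2] - r[e, 2] * cvec[e, 1]
      )
    }
    message(sprintf("material_axes: azimuthal fallback used for %d near-apex element(s)", n_degen))
  }
  structure(list(r = r, c = cvec, l = l), class = "material_frame")
}

#' Uniformly scale a mesh about the long-axis origin
#'
#' @param mesh an `lv_mesh`.
#' @param s positive scale factor.
#' @return The scaled mesh (tags, depth and provenance preserved; any
#'   attached spec is scaled consistently).
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (!.is_scalar_num(s) || s <= 0) .stopf("scale factor must be > 0")
  out <- mesh
  out$nodes <- mesh$nodes * s
  if (!is.null(mesh$spec)) {
    out$spec <- ellipsoid_spec(mesh$spec$epi * s, mesh$spec$endo * s,
                               mesh$spec$truncation_fraction, mesh$spec$unit)
  }
  out
}

# replace node coordinates (same topology), e.g. after a mechanics solve
deform_mesh <- function(mesh, new_nodes, provenance = mesh$provenance) {
  stopifnot(inherits(mesh, "lv_mesh"),
            nrow(new_nodes) == nrow(mesh$nodes), ncol(new_nodes) == 3L)
  out <- mesh
  out$nodes <- new_nodes
  out$provenance <- provenance
  out$spec <- NULL
  out
}

# intersection of a tagged surface with the plane z = z_s, as 2D segments
.surface_plane_segments <- function(nodes, tris, z_s) {
  tris <- tris[, 1:3, drop = FALSE]
  segs <- list()
  z <- matrix(nodes[tris, 3], ncol = 3L)
  crosses <- (apply(z, 1, min) <= z_s) & (apply(z, 1, max) >= z_s)
  for (i in which(crosses)) {
    vid <- tris[i, ]
    p <- nodes[vid, , drop = FALSE]
    pts <- matrix(0, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      z1 <- p[e[1], 3]; z2 <- p[e[2], 3]
      if ((z1 - z_s) * (z2 - z_s) <= 0 && abs(z2 - z1) > 1e-14) {
        t <- (z_s - z1) / (z2 - z1)
        if (t >= -1e-9 && t <= 1 + 1e-9) {
          q <- p[e[1], 1:2] + t * (p[e[2], 1:2] - p[e[1], 1:2])
          pts <- rbind(pts, q)
        }
      }
    }
    if (nrow(pts) >= 2L) {
      # keep the two most distant points (robust to touching vertices)
      if (nrow(pts) > 2L) {
        d <- as.matrix(stats::dist(pts))
        ij <- which(d == max(d), arr.ind = TRUE)[1, ]
        pts <- pts[ij, , drop = FALSE]
      }
      if (sum((pts[1, ] - pts[2, ])^2) > 1e-24) segs[[length(segs) + 1L]] <- pts
    }
  }
  segs
}

# first positive intersection distance of ray (origin o, direction d) with
# 2D segments; NA if none
.ray_hit <- function(o, d, segs) {
  best <- Inf
  for (s in segs) {
    q1 <- s[1, ]; q2 <- s[2, ]
    A <- cbind(d, q1 - q2)
    detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    if (abs(detA) < 1e-14) next
    rhs <- q1 - o
    t <- (rhs[1] * A[2, 2] - rhs[2] * A[1, 2]) / detA
    u <- (A[1, 1] * rhs[2] - A[2, 1] * rhs[1]) / detA
    if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9 && t < best) best <- t
  }
  if (is.finite(best)) best else NA_real_
}

#' Ray-based wall thickness in a short-axis slice
#'
#' Cuts the endocardial and epicardial surfaces with the short-axis plane at
#' `slice_fraction` of the long-axis length from the base, then casts
#' `n_rays` equally spaced rays from the cavity centroid of the slice and
#' averages (epicardial radius - endocardial radius) over the rays.
#'
#' @param mesh an `lv_mesh` (reference or deformed).
#' @param slice_fraction position of the slice, as a fraction of the
#'   long-axis length measured from the base (default 0.5, midventricular).
#' @param n_rays number of rays (default 4, at 90 degrees spacing).
#' @param phase azimuthal offset of the first ray in degrees (default 0,
#'   i.e. along +x).
#' @return Mean thickness; per-ray values in attribute `"per_ray"`.
#' @export
wall_thickness <- function(mesh, slice_fraction = 0.5, n_rays = 4, phase = 0) {
  stopifnot(inherits(mesh, "lv_mesh"))
  L <- -min(mesh$nodes[, 3])
  z_s <- -slice_fraction * L
  if (z_s <= -L || z_s > 0) .stopf("slice plane does not intersect the wall")
  segs_en <- .surface_plane_segments(mesh$nodes, mesh$surfaces$endocardium, z_s)
  segs_ep <- .surface_plane_segments(mesh$nodes, mesh$surfaces$epicardium, z_s)
  if (!length(segs_en) || !length(segs_ep)) {
    .stopf("slice plane at z = %.3g misses a surface", z_s)
  }
  cen <- colMeans(do.call(rbind, lapply(segs_en, colMeans)))
  ang <- .deg2rad(phase) + 2 * pi * (0:(n_rays - 1L)) / n_rays
  per_ray <- numeric(n_rays)
  for (i in seq_len(n_rays)) {
    d <- c(cos(ang[i]), sin(ang[i]))
    r_en <- .ray_hit(cen, d, segs_en)
    r_ep <- .ray_hit(cen, d, segs_ep)
    if (is.na(r_en) || is.na(r_ep)) {
      .stopf("ray %d (azimuth %.1f deg) misses a surface", i, .rad2deg(ang[i]))
    }
    per_ray[i] <- r_ep - r_en
  }
  structure(mean(per_ray), per_ray = per_ray)
}
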