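# Plain-text mesh and result I/O: Gmsh MSH v2.2 read/write, VTK XML
# (.vtu) export with cell data, and CSV tables for structure fields and
# fibre observations.  Gmsh node-ordering conventions are used on disk
# (tet10 edge order (1,2),(2,3),(1,3),(1,4),(3,4),(2,4)); the internal
# edge order is (1,2),(1,3),(1,4),(2,3),(2,4),(3,4).

# column permutation internal -> gmsh for tet10 midside nodes
.tet10_to_gmsh <- c(1:4, 5L, 8L, 6L, 7L, 10L, 9L)
.tet10_from_gmsh <- order(.tet10_to_gmsh)
# vtk quadratic tet edge order: (1,2),(2,3),(1,3),(1,4),(2,4),(3,4)
.tet10_to_vtk <- c(1:4, 5L, 8L, 6L, 7L, 9L, 10L)

.surface_tags <- c(endocardium = 1L, epicardium = 2L, base = 3L)
.volume_tag <- 10L

#' Write a mesh in Gmsh MSH v2.2 format
#'
#' Surface triangles are written with physical tags 1 (endocardium),
#' 2 (epicardium) and 3 (base); volume elements with tag 10.  The nodal
#' transmural depth field, when present, is stored as a `$NodeData`
#' block named `transmural_depth`.
#'
#' @param mesh an `lv_mesh`.
#' @param file output path (conventionally `.msh`).
#' @return The file path, invisibly.
#' @export
write_msh <- function(mesh, file) {
  stopifnot(inherits(mesh, "lv_mesh"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.16g %.16g %.16g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)

  lines <- character()
  eid <- 0L
  tri_type <- if (mesh$order == 2L) 9L else 2L
  tet_type <- if (mesh$order == 2L) 11L else 4L
  for (sname in names(mesh$surfaces)) {
    tris <- mesh$surfaces[[sname]]
    if (!nrow(tris)) next
    tag <- .surface_tags[[sname]] %||% 4L
    ids <- eid + seq_len(nrow(tris))
    lines <- c(lines, paste(ids, tri_type, 2L, tag, tag,
                            apply(tris, 1L, paste, collapse = " ")))
    eid <- eid + nrow(tris)
  }
  elems <- mesh$elems
  if (mesh$order == 2L) elems <- elems[, .tet10_to_gmsh, drop = FALSE]
  ids <- eid + seq_len(nrow(elems))
  lines <- c(lines, paste(ids, tet_type, 2L, .volume_tag, .volume_tag,
                          apply(elems, 1L, paste, collapse = " ")))
  writeLines(c("$Elements", as.character(length(lines)), lines,
               "$EndElements"), con)
  if (!is.null(mesh$node_depth)) {
    writeLines(c("$NodeData", "1", "\"transmural_depth\"", "1", "0.0", "3",
                 "0", "1", as.character(nrow(mesh$nodes))), con)
    writeLines(sprintf("%d %.16g", seq_len(nrow(mesh$nodes)),
                       mesh$node_depth), con)
    writeLines("$EndNodeData", con)
  }
  invisible(file)
}

#' Read a Gmsh MSH v2.2 mesh
#'
#' Reads tetrahedral volume elements and tagged surface triangles written
#' by [write_msh()] (physical tags 1/2/3 map to
#' endocardium/epicardium/base) and the optional `transmural_depth` node
#' data block.
#'
#' @param file path to a `.msh` file (format 2.2).
#' @param provenance provenance label for the mesh (default the file
#'   name).
#' @return An `lv_mesh`.
#' @export
read_msh <- function(file, provenance = basename(file)) {
  txt <- readLines(file)
  sec <- function(name) {
    i0 <- match(paste0("$", name), txt)
    i1 <- match(paste0("$End", name), txt)
    if (is.na(i0) || is.na(i1)) return(NULL)
    txt[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1], "2.2")) {
    .stopf("unsupported MSH format (expected version 2.2)")
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  nodetab <- matrix(scan(text = nl[-1], quiet = TRUE), nn, 4L, byrow = TRUE)
  nodes <- nodetab[order(nodetab[, 1]), 2:4, drop = FALSE]

  el <- sec("Elements")
  nelem <- as.integer(el[1])
  rows <- strsplit(el[-1][seq_len(nelem)], " +")
  tets <- list(); tris <- list(); tri_tags <- integer()
  for (r in rows) {
    v <- as.integer(r)
    type <- v[2]; ntags <- v[3]
    conn <- v[(4L + ntags):length(v)]
    tag <- if (ntags >= 1L) v[4] else 0L
    if (type %in% c(4L, 11L)) {
      tets[[length(tets) + 1L]] <- conn
    } else if (type %in% c(2L, 9L)) {
      tris[[length(tris) + 1L]] <- conn
      tri_tags <- c(tri_tags, tag)
    }
  }
  if (!length(tets)) .stopf("no tetrahedral elements in %s", file)
  elems <- do.call(rbind, tets)
  order_ <- if (ncol(elems) == 10L) 2L else 1L
  if (order_ == 2L) elems <- elems[, .tet10_from_gmsh, drop = FALSE]
  storage.mode(elems) <- "integer"
  ntri_col <- if (order_ == 2L) 6L else 3L
  surfaces <- list()
  trimat <- if (length(tris)) do.call(rbind, tris) else
    matrix(integer(), 0L, ntri_col)
  for (sname in names(.surface_tags)) {
    sel <- tri_tags == .surface_tags[[sname]]
    surfaces[[sname]] <- trimat[sel, , drop = FALSE]
  }
  depth <- NULL
  nd <- sec("NodeData")
  if (!is.null(nd)) {
    nstr <- as.integer(nd[1])
    # header: nstr strings, nreal reals, nint ints (3 ints incl. count)
    i <- 1L + nstr
    nreal <- as.integer(nd[i + 1L]); i <- i + 1L + nreal
    nint <- as.integer(nd[i + 1L]); i <- i + 1L + nint
    vals <- matrix(scan(text = nd[(i + 1L):length(nd)], quiet = TRUE),
                   ncol = 2L, byrow = TRUE)
    depth <- numeric(nn)
    depth[as.integer(vals[, 1])] <- vals[, 2]
  }
  .new_lv_mesh(nodes, elems, order_, surfaces, depth, provenance)
}

#' Export a mesh with cell data to VTK XML (.vtu, ASCII)
#'
#' @param mesh an `lv_mesh`.
#' @param file output path.
#' @param cell_data named list of per-element data: numeric vectors
#'   (scalars) or ne x 3 matrices (vectors).
#' @return The file path, invisibly.
#' @export
write_vtu <- function(mesh, file, cell_data = list()) {
  stopifnot(inherits(mesh, "lv_mesh"))
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  elems <- mesh$elems
  vtk_type <- if (mesh$order == 2L) 24L else 10L
  if (mesh$order == 2L) elems <- elems[, .tet10_to_vtk, drop = FALSE]
  npe <- ncol(elems)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("          %.10g %.10g %.10g", mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste("         ",
                   apply(elems - 1L, 1L, paste, collapse = " ")), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste("         ", seq_len(ne) * npe), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste("         ", rep(vtk_type, ne)), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      d <- cell_data[[nm]]
      if (is.matrix(d) && ncol(d) == 3L) {
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
        writeLines(sprintf("          %.10g %.10g %.10g",
                           d[, 1], d[, 2], d[, 3]), con)
      } else {
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
        writeLines(sprintf("          %.10g", as.numeric(d)), con)
      }
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a structure field as a plain-text table
#'
#' One row per element: id, helix angle theta (deg), sheet angle beta
#' (deg), region label (NA for global models) and the fibre vector.
#'
#' @param structure a `structure_field`.
#' @param file output CSV path.
#' @return The file path, invisibly.
#' @export
write_structure_table <- function(structure, file) {
  stopifnot(inherits(structure, "structure_field"))
  df <- data.frame(
    element = seq_len(nrow(structure$f)),
    theta_deg = structure$theta, beta_deg = structure$beta,
    region = structure$regions %||% NA_integer_,
    fx = structure$f[, 1], fy = structure$f[, 2], fz = structure$f[, 3]
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write / read fibre-direction observations as CSV
#'
#' Columns: element, vx, vy, vz.
#'
#' @param observations a `fibre_observations` or an ne x 3 matrix.
#' @param file CSV path.
#' @return `write_observations` the path invisibly; `read_observations`
#'   an ne x 3 matrix of unit vectors.
#' @export
write_observations <- function(observations, file) {
  v <- if (inherits(observations, "fibre_observations")) {
    observations$vectors
  } else {
    observations
  }
  df <- data.frame(element = seq_len(nrow(v)), vx = v[, 1], vy = v[, 2],
                   vz = v[, 3])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_observations
#' @export
read_observations <- function(file) {
  df <- utils::read.csv(file)
  m <- as.matrix(df[order(df$element), c("vx", "vy", "vz")])
  dimnames(m) <- NULL
  m
}

#' Write / read a simulation configuration as YAML
#'
#' Serializes the scalar parameters of a [simulation_config()] (geometry
#' semi-axes, fibre/sheet model, material law, electrophysiology, pressure
#' trace, twitch and timing) to a structured text file and rebuilds the
#' config from it.
#'
#' @param config a `simulation_config`.
#' @param file YAML path.
#' @return `write_sim_config` the path invisibly; `read_sim_config` a
#'   `simulation_config`.
#' @export
write_sim_config <- function(config, file) {
  stopifnot(inherits(config, "simulation_config"))
  x <- list(
    geometry = list(
      pre_p = list(epi = config$geometry$pre_p$epi,
                   endo = config$geometry$pre_p$endo),
      post_p = list(epi = config$geometry$post_p$epi,
                    endo = config$geometry$post_p$endo)
    ),
    mech_divisions = unname(config$mech_divisions),
    ep_divisions = unname(config$ep_divisions),
    fibre = list(R = config$fibre$R, n = config$fibre$n,
                 kind = config$fibre$kind),
    sheet = list(kind = config$sheet$kind,
                 beta_endo = config$sheet$beta_endo,
                 beta_epi = config$sheet$beta_epi, k = config$sheet$k),
    law = list(C0 = config$law$C0, b = unname(config$law$b),
               kappa = config$law$kappa, symmetry = config$law$symmetry),
    ep = unclass(config$ep_params),
    stim = list(apical_fraction = config$stim$apical_fraction,
                amplitude = config$stim$amplitude,
                duration = config$stim$duration, start = config$stim$start),
    trace = unclass(config$trace),
    twitch = unclass(config$twitch),
    duration = config$duration, dt_mech = config$dt_mech,
    sample_every = config$sample_every, seed = config$seed
  )
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  x <- yaml::read_yaml(file)
  fib <- if (identical(x$fibre$kind, "regional")) {
    regional_fibre_model(x$fibre$R, x$fibre$n)
  } else {
    fibre_model(x$fibre$R, x$fibre$n)
  }
  simulation_config(
    geometry = list(
      pre_p = ellipsoid_spec(x$geometry$pre_p$epi, x$geometry$pre_p$endo),
      post_p = ellipsoid_spec(x$geometry$post_p$epi, x$geometry$post_p$endo)
    ),
    mech_divisions = x$mech_divisions,
    ep_divisions = x$ep_divisions,
    fibre = fib,
    sheet = sheet_model(x$sheet$kind, x$sheet$beta_endo, x$sheet$beta_epi,
                        x$sheet$k),
    law = material_law(x$law$C0, x$law$b, x$law$kappa, x$law$symmetry),
    ep_params = monodomain_params(x$ep$C_m, x$ep$chi, x$ep$sigma_f,
                                  x$ep$sigma_s, x$ep$sigma_n, x$ep$dt_ode,
                                  x$ep$dt_pde),
    stim = stimulus_protocol(x$stim$apical_fraction, x$stim$amplitude,
                             x$stim$duration, x$stim$start),
    trace = pressure_trace(x$trace$p_end, x$trace$t_mid, x$trace$tau),
    twitch = twitch_params(x$twitch$T_max, x$twitch$t_twitch,
                           x$twitch$threshold),
    duration = x$duration, dt_mech = x$dt_mech,
    sample_every = x$sample_every, seed = x$seed
  )
}

#' Export a sampled simulation result to disk
#'
#' Writes, into `dir`: a VTU file per sample (deformed mesh with the
#' per-element Jacobian of the centroid deformation gradient as cell
#' data), the cavity-volume/pressure trace as CSV, and a JSON provenance
#' record (provenance hash, seed, sample times, package version).
#'
#' @param result a `simulation_result`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation_result <- function(result, dir) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(result$times)) {
    Fm <- result$F[[k]]
    J <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 6] * Fm[, 8]) -
      Fm[, 2] * (Fm[, 4] * Fm[, 9] - Fm[, 6] * Fm[, 7]) +
      Fm[, 3] * (Fm[, 4] * Fm[, 8] - Fm[, 5] * Fm[, 7])
    mesh_k <- deform_mesh(result$mesh, result$nodes[[k]])
    write_vtu(mesh_k, file.path(dir, sprintf("state_%04d.vtu", k - 1L)),
              cell_data = list(jacobian = J))
  }
  write_volume_trace(result, file.path(dir, "volume_trace.csv"))
  prov <- list(
    provenance = result$provenance %||% NA_character_,
    seed = result$config$seed %||% NA_integer_,
    times_ms = result$times,
    package_version = as.character(utils::packageVersion("lvemech"))
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
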