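# One-way coupled electromechanical simulation: electrophysiology on the
# refined passive-pressurized geometry produces a nodal activation map,
# which is mapped onto the mechanics elements and drives a parametric
# active-tension twitch; mechanics is marched as a sequence of warm-started
# quasi-static solves under the sigmoidal cavity-pressure trace.

#' Sigmoidal cavity-pressure trace
#'
#' p(t) = p_end / (1 + exp(-(t - t_mid)/tau)): a monotone sigmoid from
#' (almost) zero to the plateau magnitude `p_end`, applied inward on the
#' endocardium.
#'
#' @param p_end plateau pressure magnitude (kPa, default 1).
#' @param t_mid half-rise time (ms, default 30).
#' @param tau steepness time constant (ms, default 6).
#' @return Object of class `pressure_trace`.
#' @export
pressure_trace <- function(p_end = 1, t_mid = 30, tau = 6) {
  if (p_end < 0 || tau <= 0) .stopf("require p_end >= 0 and tau > 0")
  structure(list(p_end = p_end, t_mid = t_mid, tau = tau),
            class = "pressure_trace")
}

#' Cavity pressure at a time point
#'
#' @param t time(s) in ms (>= 0).
#' @param trace a [pressure_trace()].
#' @return Pressure magnitude(s) in kPa.
#' @export
pressure_at <- function(t, trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  trace$p_end / (1 + exp(-(t - trace$t_mid) / trace$tau))
}

#' Active-tension twitch parameters
#'
#' The cellular contraction is represented by a squared-sine twitch:
#' T_a(t) = T_max sin^2(pi (t - t_act) / t_twitch) for
#' t_act <= t <= t_act + t_twitch and 0 otherwise, triggered at the local
#' electrical activation time.
#'
#' @param T_max peak tension (kPa, default 35).
#' @param t_twitch twitch duration (ms, default 90, rodent-like short
#'   contraction).
#' @param threshold activation-detection voltage (mV, default -20).
#' @return Object of class `twitch_params`.
#' @export
twitch_params <- function(T_max = 35, t_twitch = 90, threshold = -20) {
  if (T_max < 0 || t_twitch <= 0) .stopf("require T_max >= 0 and t_twitch > 0")
  structure(list(T_max = T_max, t_twitch = t_twitch, threshold = threshold),
            class = "twitch_params")
}

#' Active tension at a time point
#'
#' @param t time (ms, scalar).
#' @param t_act activation time(s) (ms); vectorized, NA gives zero
#'   tension.
#' @param params a [twitch_params()].
#' @return Tension(s) in kPa.
#' @export
active_tension <- function(t, t_act, params) {
  stopifnot(inherits(params, "twitch_params"))
  tau <- t - t_act
  out <- ifelse(!is.na(tau) & tau >= 0 & tau <= params$t_twitch,
                params$T_max * sin(pi * tau / params$t_twitch)^2, 0)
  out[is.na(out)] <- 0
  out
}

#' Configuration of a coupled electromechanical simulation
#'
#' @param geometry list with `ellipsoid_spec` entries `pre_p` (mechanics)
#'   and `post_p` (electrophysiology); default [rat_lv_geometry()].
#' @param mech_divisions `c(nr, ntheta, nz)` for the quadratic mechanics
#'   mesh (default c(2, 12, 6)).
#' @param ep_divisions divisions for the linear electrophysiology mesh,
#'   built on the post-P geometry (default twice the mechanics
#'   divisions).
#' @param fibre a [fibre_model()] or [regional_fibre_model()] (default
#'   Sn1R70).
#' @param sheet a [sheet_model()] (default linear).
#' @param law a [material_law()] (default transversely isotropic).
#' @param ep_params a [monodomain_params()].
#' @param stim a [stimulus_protocol()] (default apical 15 percent).
#' @param trace a [pressure_trace()].
#' @param twitch a [twitch_params()].
#' @param duration simulated time (ms, default 60, approximately the time
#'   at which full contraction is achieved for the default twitch and
#'   activation sequence).
#' @param dt_mech mechanics step (ms, default 1).
#' @param sample_every sampling interval (ms, default 2).
#' @param seed integer seed recorded with the run (the default pipeline is
#'   deterministic; the seed feeds any synthetic-data stage).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = rat_lv_geometry(),
                              mech_divisions = c(2, 12, 6),
                              ep_divisions = NULL,
                              fibre = fibre_model(70, 1),
                              sheet = sheet_model("linear"),
                              law = law_transverse_isotropic(),
                              ep_params = monodomain_params(),
                              stim = stimulus_protocol(),
                              trace = pressure_trace(),
                              twitch = twitch_params(),
                              duration = 60, dt_mech = 1,
                              sample_every = 2, seed = 1L) {
  if (is.null(ep_divisions)) ep_divisions <- 2L * as.integer(mech_divisions)
  structure(
    list(geometry = geometry, mech_divisions = as.integer(mech_divisions),
         ep_divisions = as.integer(ep_divisions), fibre = fibre,
         sheet = sheet, law = law, ep_params = ep_params, stim = stim,
         trace = trace, twitch = twitch, duration = duration,
         dt_mech = dt_mech, sample_every = sample_every,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic content hash of a config (provenance)
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

# map nodal EP activation times onto mechanics element centroids
# (nearest EP node)
.map_activation <- function(mech_mesh, ep_mesh, t_act) {
  el <- mech_mesh$elems[, 1:4, drop = FALSE]
  cen <- cbind(
    rowMeans(matrix(mech_mesh$nodes[el, 1], ncol = 4L)),
    rowMeans(matrix(mech_mesh$nodes[el, 2], ncol = 4L)),
    rowMeans(matrix(mech_mesh$nodes[el, 3], ncol = 4L))
  )
  P <- ep_mesh$nodes
  out <- numeric(nrow(cen))
  # chunked brute-force nearest neighbour
  chunk <- 256L
  for (s in seq(1L, nrow(cen), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(cen))
    d2 <- outer(rowSums(cen[idx, , drop = FALSE]^2), rowSums(P^2), "+") -
      2 * cen[idx, , drop = FALSE] %*% t(P)
    out[idx] <- t_act[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Run the coupled electromechanical simulation
#'
#' Pipeline stages: (1) build the quadratic mechanics mesh on the
#' unloaded (pre-P) geometry and the finer linear electrophysiology mesh
#' on the passively pressurized (post-P) geometry; (2) generate the
#' fibre/sheet structure on both; (3) solve the monodomain equations with
#' apical stimulation (unless a precomputed `activation` map is supplied
#' -- the coupling is one-way, so the electrical solution is independent
#' of all mechanical parameters and may be shared between material-law
#' variants); (4) march the mechanics in time under the pressure trace
#' and the per-element activation-triggered twitch, warm-starting each
#' quasi-static solve; (5) sample mesh state, deformation gradients and
#' cavity volume.
#'
#' @param config a [simulation_config()].
#' @param activation optional precomputed per-mechanics-element activation
#'   times (ms), bypassing the electrophysiology stage.
#' @param verbose print stage progress.
#' @return Object of class `simulation_result` with fields `times`,
#'   `nodes` (list of sampled node coordinates), `F` (list of ne x 9
#'   centroid deformation gradients), `volumes`, `pressures`, `mesh`
#'   (reference mechanics mesh), `structure`, `activation`, `config` and
#'   `provenance` (config hash).
#' @export
run_simulation <- function(config, activation = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("simulation stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  set.seed(config$seed)

  say("stage 1: meshes")
  mech_mesh <- stage("geometry", build_lv_mesh(
    config$geometry$pre_p, order = 2, divisions = config$mech_divisions,
    provenance = "pre-P"
  ))
  structure_mech <- stage("structure", build_structure_field(
    mech_mesh, fibre = config$fibre, sheet = config$sheet
  ))

  if (is.null(activation)) {
    say("stage 2: electrophysiology")
    ep_mesh <- stage("geometry", build_lv_mesh(
      config$geometry$post_p, order = 1, divisions = config$ep_divisions,
      provenance = "post-P"
    ))
    structure_ep <- stage("structure", build_structure_field(
      ep_mesh, fibre = config$fibre, sheet = config$sheet
    ))
    ep <- stage("electrophysiology", solve_monodomain(
      ep_mesh, structure_ep, config$ep_params, config$stim,
      duration = min(config$duration, 60),
      sample_interval = config$sample_every
    ))
    activation <- stage("activation mapping",
                        .map_activation(mech_mesh, ep_mesh, ep$activation))
  } else {
    if (length(activation) != nrow(mech_mesh$elems)) {
      .stopf("supplied activation map does not match the mechanics mesh")
    }
  }

  say("stage 3: mechanics march")
  bc <- .base_constraints(mech_mesh)
  dirichlet <- list(dofs = bc$fixed, vals = bc$fixed_vals)
  rigid_penalty <- boundary_spec()$rigid_penalty
  nt <- as.integer(round(config$duration / config$dt_mech))
  sample_every <- max(1L, as.integer(round(config$sample_every / config$dt_mech)))

  u <- NULL
  p_prev <- 0
  Ta_prev <- numeric(nrow(mech_mesh$elems))
  times <- 0
  nodes_s <- list(mech_mesh$nodes)
  F0 <- mech_deformation(mech_mesh$nodes, mech_mesh$elems - 1L,
                         matrix(0, nrow(mech_mesh$nodes), 3L))
  F_s <- list(F0)
  vols <- mesh_volumes(mech_mesh)[["cavity"]]
  prs <- 0
  for (k in seq_len(nt)) {
    t_k <- k * config$dt_mech
    p_k <- pressure_at(t_k, config$trace)
    Ta_k <- active_tension(t_k, activation, config$twitch)
    sol <- stage("mechanics", .solve_loadpath(
      mech_mesh, structure_mech, config$law, p_k, Ta_k, dirichlet,
      bc$agg, rigid_penalty, u0 = u, pressure0 = p_prev, Ta0 = Ta_prev
    ))
    u <- sol$disp
    p_prev <- p_k
    Ta_prev <- Ta_k
    if (k %% sample_every == 0L || k == nt) {
      def_nodes <- mech_mesh$nodes + u
      times <- c(times, t_k)
      nodes_s[[length(nodes_s) + 1L]] <- def_nodes
      F_s[[length(F_s) + 1L]] <- mech_deformation(mech_mesh$nodes,
                                                  mech_mesh$elems - 1L, u)
      vols <- c(vols, .cavity_volume(def_nodes,
                                     mech_mesh$surfaces$endocardium))
      prs <- c(prs, p_k)
    }
  }
  structure(
    list(times = times, nodes = nodes_s, F = F_s, volumes = vols,
         pressures = prs, mesh = mech_mesh, structure = structure_mech,
         activation = activation, config = config,
         provenance = .config_hash(config)),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation result: %d samples over %g ms; cavity volume %.4g -> %.4g\n",
    length(x$times), max(x$times), x$volumes[1], x$volumes[length(x$volumes)]
  ))
  invisible(x)
}

#' Write the volume/pressure traces of a simulation result to CSV
#'
#' @param result a `simulation_result`.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_volume_trace <- function(result, file) {
  df <- data.frame(time_ms = result$times, cavity_volume = result$volumes,
                   pressure_kPa = result$pressures)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
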