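# Phenomenological two-variable cell model.
#
# The tissue pipeline only requires a propagating activation wave with a
# tunable action-potential duration, so the cellular electrophysiology is
# represented by a two-variable excitation/recovery model in the
# Mitchell-Schaeffer family: a normalized excitation variable v in [0, 1]
# with a cubic-like upstroke and a recovery gate h.  The transmembrane
# voltage is an affine map V = V_rest + A * v.  Any model exposing an
# initial state and a right-hand side with the same interface can be
# plugged into the monodomain solver.

#' Two-variable phenomenological action-potential model
#'
#' dv/dt = h v^2 (1 - v) / tau_in - v / tau_out + I,
#' dh/dt = (1 - h) / tau_open below the gate threshold, -h / tau_close
#' above it.  Defaults are tuned for a rodent-like short action potential
#' (duration of roughly 50 ms above the -20 mV mapping threshold) with a
#' sub-millisecond upstroke.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants (ms).
#' @param v_gate gate threshold on the normalized voltage.
#' @param V_rest resting voltage (mV).
#' @param A action-potential amplitude (mV).
#' @return Object of class `cell_model` with fields `init` (named numeric
#'   state) and `rhs(state, I)`.
#' @export
cell_model_ms <- function(tau_in = 0.2, tau_out = 9, tau_open = 80,
                          tau_close = 19, v_gate = 0.13,
                          V_rest = -80, A = 100) {
  force(tau_in); force(tau_out); force(tau_open); force(tau_close)
  force(v_gate)
  m <- list(
    name = "two-variable phenomenological",
    init = c(v = 0, h = 1),
    n_state = 2L,
    V_rest = V_rest, A = A,
    v_gate = v_gate,
    pars = c(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
             tau_close = tau_close),
    rhs = function(state, I = 0) {
      v <- state$v; h <- state$h
      dv <- h * v * v * (1 - v) / tau_in - v / tau_out + I
      dh <- ifelse(v < v_gate, (1 - h) / tau_open, -h / tau_close)
      list(v = dv, h = dh)
    }
  )
  class(m) <- "cell_model"
  m
}

#' Initial (resting) cell state
#'
#' @param model a `cell_model`.
#' @param n number of copies (nodes); state variables are vectors of
#'   length `n`.
#' @return Object of class `cell_state`: named list of state vectors plus
#'   the model.
#' @export
cell_state <- function(model = cell_model_ms(), n = 1L) {
  st <- lapply(model$init, function(x0) rep(x0, n))
  structure(list(state = st, model = model), class = "cell_state")
}

#' Map the normalized excitation variable to transmembrane voltage (mV)
#' @param state a `cell_state`.
#' @return Numeric vector of voltages.
#' @export
cell_voltage <- function(state) {
  state$model$V_rest + state$model$A * state$state$v
}

#' Advance the cell model by one explicit step
#'
#' Forward-Euler step of the cell ODE system; `I_stim` is expressed in
#' normalized-voltage units per ms (the tissue solver performs the
#' conversion from a volumetric current density).
#'
#' @param state a `cell_state` (possibly vectorized over nodes).
#' @param I_stim stimulus in normalized units (scalar or per-node vector).
#' @param dt step size (ms).
#' @return Updated `cell_state`.
#' @export
step_cell <- function(state, I_stim = 0, dt) {
  stopifnot(inherits(state, "cell_state"))
  d <- state$model$rhs(state$state, I_stim)
  new <- mapply(function(x, dx) x + dt * dx, state$state, d, SIMPLIFY = FALSE)
  if (any(!vapply(new, function(x) all(is.finite(x)), logical(1)))) {
    .stopf("non-finite cell state after step (dt = %g)", dt)
  }
  state$state <- new
  state
}

#' Integrate a single cell over a time interval
#'
#' @param model a `cell_model`.
#' @param duration total time (ms).
#' @param dt step (ms).
#' @param stim function(t) returning the normalized stimulus at time t
#'   (default none).
#' @return Data frame with columns `t`, `V` and the state variables.
#' @export
run_cell <- function(model = cell_model_ms(), duration = 100, dt = 0.01,
                     stim = function(t) 0) {
  nsteps <- as.integer(round(duration / dt))
  st <- cell_state(model, 1L)
  out_t <- seq(0, duration, by = dt)
  V <- numeric(nsteps + 1L)
  v <- numeric(nsteps + 1L)
  h <- numeric(nsteps + 1L)
  V[1] <- cell_voltage(st); v[1] <- st$state$v; h[1] <- st$state$h
  for (i in seq_len(nsteps)) {
    st <- step_cell(st, stim((i - 1) * dt), dt)
    V[i + 1] <- cell_voltage(st); v[i + 1] <- st$state$v; h[i + 1] <- st$state$h
  }
  data.frame(t = out_t, V = V, v = v, h = h)
}
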