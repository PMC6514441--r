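# --- internal: flatten channels into the numeric matrix the C++ integrator uses ---

.gate_cols <- function(gate) {
  if (is.null(gate)) return(rep(0, 7))
  c(gate$vhalf, gate$k, gate$tau_min, gate$tau_amp, gate$tau_vhalf, gate$tau_k1, gate$tau_k2)
}

.compile_channels <- function(params) {
  chs <- params$channels
  mat <- matrix(0, nrow = length(chs), ncol = 21,
                dimnames = list(names(chs), NULL))
  for (i in seq_along(chs)) {
    ch <- chs[[i]]
    akind <- if (ch$calcium_dependent) 2 else if (!is.null(ch$activation)) 1 else 0
    act <- if (ch$calcium_dependent)
      c(ch$calcium_gate$kd, ch$calcium_gate$hill, ch$calcium_gate$tau, 0, 0, 0, 0)
    else .gate_cols(ch$activation)
    mat[i, ] <- c(ch$g_max, ch$e_rev, ch$p, ch$q, akind,
                  as.numeric(!is.null(ch$inactivation)),
                  as.numeric(ch$is_ca_source),
                  act, .gate_cols(ch$inactivation))
  }
  mat
}

# --- neuron state ---------------------------------------------------------------

#' Initialize a neuron state at its voltage-clamped steady state
#'
#' All gating variables are set to their steady-state values at \code{v0} and
#' the calcium concentration to its fixed point given the steady CaL current at
#' \code{v0}. Starting protocols from this state (plus the matching bias
#' current) avoids long equilibration transients.
#'
#' @param params a \code{tspn_neuron}.
#' @param v0 initial membrane potential in mV (within [-120, 0]).
#' @return a \code{tspn_state}: list with \code{v}, \code{gates} (channels x 2
#'   matrix of activation/inactivation values), \code{ca} (uM) and \code{t}.
#' @export
steady_state_init <- function(params, v0) {
  stopifnot(inherits(params, "tspn_neuron"))
  if (v0 < -120 || v0 > 0) stop("v0 must lie in [-120, 0] mV")
  chs <- params$channels
  gates <- matrix(1, nrow = length(chs), ncol = 2,
                  dimnames = list(names(chs), c("m", "h")))
  for (i in seq_along(chs)) {
    ch <- chs[[i]]
    if (!is.null(ch$activation)) gates[i, 1] <- gate_inf(v0, ch$activation)
    if (!is.null(ch$inactivation)) gates[i, 2] <- gate_inf(v0, ch$inactivation)
  }
  # calcium fixed point from the steady CaL current, then the KCa gate from it
  cal <- chs$CaL
  i_cal <- if (is.null(cal)) 0 else
    cal$g_max * gates["CaL", 1]^cal$p * (v0 - cal$e_rev)
  ca <- max(0, -params$calcium$alpha * i_cal / params$calcium$k_removal)
  for (i in seq_along(chs))
    if (chs[[i]]$calcium_dependent) gates[i, 1] <- ca_gate_inf(ca, chs[[i]]$calcium_gate)
  structure(list(v = v0, gates = gates, ca = ca, t = 0), class = "tspn_state")
}

# --- instantaneous quantities ---------------------------------------------------

#' Instantaneous current through one channel
#'
#' Evaluates \eqn{I = G m^p h^q (V - E)} for a single channel at a given state
#' (outward current positive). For the calcium-dependent KCa channel the
#' activation value is taken from the state's gate entry, which is driven by
#' the calcium concentration during integration.
#'
#' @param ch a channel specification (an element of \code{params$channels}).
#' @param state a \code{tspn_state}.
#' @return current in pA.
#' @export
channel_current <- function(ch, state) {
  g <- ch$g_max
  if (ch$p > 0) g <- g * state$gates[ch$name, 1]^ch$p
  if (ch$q > 0) g <- g * state$gates[ch$name, 2]^ch$q
  g * (state$v - ch$e_rev)
}

#' Membrane and calcium derivatives at a state
#'
#' Right-hand side of the model: \eqn{dV/dt = (-\sum_i I_i - I_{syn} +
#' I_{inj})/C_m} with injected current depolarizing-positive, and
#' \eqn{d[Ca]/dt = \lambda(-\alpha I_{CaL} - k_{CaS}[Ca])}.
#'
#' @param params a \code{tspn_neuron}.
#' @param state a \code{tspn_state}.
#' @param i_inj injected current in pA (positive depolarizes).
#' @param g_syn synaptic conductance in nS.
#' @param e_syn synaptic reversal potential in mV (default 0).
#' @return list with \code{dv} (mV/ms) and \code{dca} (uM/ms).
#' @export
membrane_derivative <- function(params, state, i_inj = 0, g_syn = 0, e_syn = 0) {
  tot <- sum(vapply(params$channels, channel_current, numeric(1), state = state))
  i_syn <- g_syn * (state$v - e_syn)
  i_cal <- if (is.null(params$channels$CaL)) 0 else
    channel_current(params$channels$CaL, state)
  list(dv = (-tot - i_syn + i_inj) / params$c_m,
       dca = params$calcium$lambda *
         (-params$calcium$alpha * i_cal - params$calcium$k_removal * state$ca))
}

# --- integration ----------------------------------------------------------------

#' Integrate the model with the exponential-Euler method
#'
#' Advances gating variables by the exact exponential update
#' \eqn{x \leftarrow x_\infty + (x - x_\infty) e^{-dt/\tau_x}} and the membrane
#' potential by exponential Euler, using the instantaneous total conductance as
#' decay rate and the conductance-weighted reversal (plus injected current) as
#' target. The calcium pool is advanced the same way from the instantaneous CaL
#' current. Default time step 0.1 ms.
#'
#' @param params a \code{tspn_neuron}.
#' @param i_inj numeric vector of injected current samples (pA); its length
#'   determines the duration \code{length(i_inj) * dt}.
#' @param g_syn optional synaptic conductance samples (nS), same length.
#' @param init initial \code{tspn_state}; default: steady state at -65 mV.
#' @param dt time step in ms.
#' @param e_syn synaptic reversal potential (mV).
#' @param record_gates,record_ca record the full gate / calcium time courses.
#' @param meta optional list of protocol metadata stored on the trace.
#' @return a \code{tspn_trace}: list with \code{dt}, \code{v}, \code{i_inj},
#'   \code{g_syn}, \code{ca}, final state \code{state}, and \code{meta}.
#'   Sample \code{i} corresponds to time \code{i * dt}.
#' @export
tspn_integrate <- function(params, i_inj, g_syn = NULL, init = NULL, dt = 0.1,
                           e_syn = 0, record_gates = FALSE, record_ca = FALSE,
                           meta = list()) {
  stopifnot(inherits(params, "tspn_neuron"), dt > 0)
  if (is.null(init)) init <- steady_state_init(params, -65)
  if (!is.null(g_syn) && length(g_syn) != length(i_inj))
    stop("g_syn and i_inj must have equal length")
  if (any(init$gates < 0 | init$gates > 1)) stop("initial gates must lie in [0, 1]")
  res <- .integrate_cpp(.compile_channels(params), params$c_m,
                        params$calcium$lambda, params$calcium$alpha,
                        params$calcium$k_removal,
                        init$v, init$gates, init$ca,
                        as.numeric(i_inj),
                        if (is.null(g_syn)) numeric(0) else as.numeric(g_syn),
                        e_syn, dt, record_gates, record_ca)
  gates <- res$gates
  dimnames(gates) <- dimnames(init$gates)
  state <- structure(list(v = res$v_end, gates = gates, ca = res$ca,
                          t = init$t + length(i_inj) * dt), class = "tspn_state")
  structure(list(dt = dt, v = res$v, i_inj = as.numeric(i_inj),
                 g_syn = g_syn, ca = if (record_ca) res$ca_trace else NULL,
                 gates_trace = if (record_gates) res$gates_trace else NULL,
                 state = state, meta = meta),
            class = "tspn_trace")
}

#' Simulate a model neuron
#'
#' \code{simulate} method for \code{tspn_neuron}: runs the exponential-Euler
#' integrator for a stimulus given either as a current vector or as a
#' step-protocol description (see \code{\link{step_stimulus}}).
#'
#' @param object a \code{tspn_neuron}.
#' @param nsim number of traces (each is an identical deterministic run unless
#'   the stimulus carries randomness; kept for generic compatibility).
#' @param seed optional seed, applied before building stochastic stimuli.
#' @param stimulus either a numeric vector of injected current (pA) or a list
#'   produced by \code{\link{step_stimulus}}.
#' @param ... passed to \code{\link{tspn_integrate}}.
#' @return a \code{tspn_trace} (or a list of them when \code{nsim > 1}).
#' @export
simulate.tspn_neuron <- function(object, nsim = 1, seed = NULL, stimulus, ...) {
  if (!is.null(seed)) set.seed(seed)
  run1 <- function() {
    if (is.list(stimulus) && !is.null(stimulus$i_inj))
      tspn_integrate(object, stimulus$i_inj, dt = stimulus$dt,
                     meta = stimulus$meta, ...)
    else tspn_integrate(object, stimulus, ...)
  }
  if (nsim == 1) run1() else replicate(nsim, run1(), simplify = FALSE)
}

#' @export
print.tspn_trace <- function(x, ...) {
  cat(sprintf("tSPN trace: %d samples, dt = %g ms (%.1f ms), V in [%.1f, %.1f] mV\n",
              length(x$v), x$dt, length(x$v) * x$dt, min(x$v), max(x$v)))
  if (length(x$meta)) {
    keys <- vapply(x$meta, function(v) paste(format(v), collapse = " "), character(1))
    cat("  meta:", paste(names(keys), keys, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.tspn_trace <- function(x, show_current = TRUE, ...) {
  t <- seq_along(x$v) * x$dt
  if (show_current && length(unique(x$i_inj)) > 1) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    plot(t, x$v, type = "l", xlab = "", ylab = "V (mV)", ...)
    plot(t, x$i_inj, type = "l", xlab = "time (ms)", ylab = "I (pA)")
  } else {
    plot(t, x$v, type = "l", xlab = "time (ms)", ylab = "V (mV)", ...)
  }
  invisible(x)
}

#' Time axis of a trace
#' @param trace a \code{tspn_trace}.
#' @return time of each sample in ms.
#' @export
trace_time <- function(trace) seq_along(trace$v) * trace$dt
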