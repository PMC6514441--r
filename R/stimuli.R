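#' Build a current-step stimulus
#'
#' Constant bias current throughout, plus a square step of \code{step_pa} on
#' top of the bias between \code{onset} and \code{onset + step_ms}. The step
#' window is stored in the metadata and used by the classification and
#' feature-extraction routines.
#'
#' @param bias_pa holding bias current in pA (see \code{\link{find_bias_current}}).
#' @param step_pa step amplitude in pA (positive depolarizes).
#' @param settle_ms pre-step settling time at bias only.
#' @param step_ms step duration; rheobase and f-I protocols use >= 1500 ms.
#' @param post_ms post-step time at bias only.
#' @param dt time step in ms.
#' @return list with \code{i_inj}, \code{dt}, \code{window} (step on/off in ms)
#'   and \code{meta}.
#' @export
step_stimulus <- function(bias_pa = 0, step_pa = 0, settle_ms = 500,
                          step_ms = 1500, post_ms = 0, dt = 0.1) {
  stopifnot(settle_ms >= 0, step_ms > 0, post_ms >= 0, dt > 0)
  n_settle <- round(settle_ms / dt)
  n_step <- round(step_ms / dt)
  n_post <- round(post_ms / dt)
  i_inj <- c(rep(bias_pa, n_settle), rep(bias_pa + step_pa, n_step),
             rep(bias_pa, n_post))
  window <- c(on = n_settle * dt, off = (n_settle + n_step) * dt)
  list(i_inj = i_inj, dt = dt, window = window,
       meta = list(bias_pa = bias_pa, step_pa = step_pa, window = window))
}

#' Unit-amplitude double-exponential synaptic conductance kernel
#'
#' \eqn{g(t) = s (e^{-t/\tau_d} - e^{-t/\tau_r})} with the scale factor s
#' computed in closed form from the peak time
#' \eqn{t_{peak} = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)} so the
#' kernel peaks at exactly 1 (nS, before per-event amplitude scaling).
#'
#' @param tau_rise,tau_decay rise and decay time constants in ms
#'   (defaults 1 and 15, as estimated from voltage-clamp recordings of
#'   spontaneous synaptic events); \code{tau_decay > tau_rise > 0}.
#' @param dt sample interval in ms.
#' @param duration kernel duration in ms (default: 8 decay constants).
#' @return numeric vector of conductance samples starting at t = 0.
#' @export
synaptic_kernel <- function(tau_rise = 1, tau_decay = 15, dt = 0.1,
                            duration = 8 * tau_decay) {
  if (!(tau_decay > tau_rise) || tau_rise <= 0)
    stop("need tau_decay > tau_rise > 0")
  t <- seq(0, duration, by = dt)
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  s <- 1 / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
  s * (exp(-t / tau_decay) - exp(-t / tau_rise))
}

#' Poisson synaptic event train
#'
#' Event times are drawn from a homogeneous Poisson process and event
#' amplitudes from a log-normal distribution (positive and right-skewed, as
#' observed for spontaneous synaptic conductances). All randomness is governed
#' by the explicit \code{seed}.
#'
#' @param rate_hz mean event rate in Hz.
#' @param duration_ms train duration in ms.
#' @param amp_meanlog,amp_sdlog log-normal amplitude parameters (nS scale);
#'   defaults give a median of ~0.6 nS with occasional multi-nS events.
#' @param tau_rise,tau_decay kernel time constants (ms).
#' @param e_syn synaptic reversal potential (mV, default 0).
#' @param seed integer seed.
#' @return a \code{tspn_syn_train}: list with \code{event_times} (ms),
#'   \code{amplitudes} (nS) and the kernel/reversal parameters.
#' @export
synaptic_event_train <- function(rate_hz = 25, duration_ms = 4000, amp_meanlog = log(0.6),
                                 amp_sdlog = 0.9, tau_rise = 1, tau_decay = 15,
                                 e_syn = 0, seed = 1) {
  stopifnot(rate_hz >= 0, duration_ms > 0)
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_ms / 1000)
  times <- sort(runif(n, 0, duration_ms))
  amps <- rlnorm(n, amp_meanlog, amp_sdlog)
  structure(list(event_times = times, amplitudes = amps, tau_rise = tau_rise,
                 tau_decay = tau_decay, e_syn = e_syn, seed = seed),
            class = "tspn_syn_train")
}

#' Dense synaptic conductance waveform from an event train
#'
#' Linear superposition of amplitude-scaled unit kernels at the event times,
#' sampled on a regular grid (the integrator consumes the dense waveform; no
#' event-driven solver is used).
#'
#' @param train a \code{tspn_syn_train} (or any list with \code{event_times},
#'   \code{amplitudes}, \code{tau_rise}, \code{tau_decay}).
#' @param dt sample interval (ms).
#' @param duration total duration (ms).
#' @return numeric vector of conductance samples (nS) of length
#'   \code{round(duration/dt)}.
#' @export
generate_synaptic_conductance <- function(train, dt = 0.1, duration) {
  n <- round(duration / dt)
  g <- numeric(n)
  if (length(train$event_times) == 0) return(g)
  kern <- synaptic_kernel(train$tau_rise, train$tau_decay, dt = dt)
  nk <- length(kern)
  for (j in seq_along(train$event_times)) {
    i0 <- floor(train$event_times[j] / dt) + 1
    if (i0 > n) next
    idx <- i0:min(n, i0 + nk - 1)
    g[idx] <- g[idx] + train$amplitudes[j] * kern[seq_along(idx)]
  }
  g
}

#' Synaptic current
#'
#' \eqn{I_{syn} = A\, g_{syn} (V - E_{syn})} in pA (outward positive; with
#' \code{e_syn = 0} the current is inward/depolarizing at rest).
#'
#' @param g_syn synaptic conductance (nS, >= 0).
#' @param amplitude dimensionless scale factor A.
#' @param v membrane potential (mV).
#' @param e_syn synaptic reversal potential (mV).
#' @export
synaptic_current <- function(g_syn, amplitude = 1, v, e_syn = 0) {
  if (any(g_syn < 0)) stop("g_syn must be >= 0")
  amplitude * g_syn * (v - e_syn)
}
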