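# Electrophysiology feature extraction: passive-property fits, spike detection
# and threshold, AP/AHP metrics, firing rates and adaptation, sag/rebound/notch
# flags. Works on traces produced by the simulator or read from disk.

#' Detect spike times in a voltage trace
#'
#' Upward crossings of \code{threshold} (default 0 mV) with a refractory
#' lockout (default 2 ms), robust for full-height model action potentials; the
#' threshold is configurable for stunted spikes.
#'
#' @param trace a \code{tspn_trace}, or a numeric voltage vector with
#'   \code{dt} supplied.
#' @param threshold crossing threshold in mV.
#' @param lockout_ms minimum separation between detected spikes (ms).
#' @param dt sample interval (ms), when \code{trace} is a bare vector.
#' @return spike times in ms (time of the first suprathreshold sample).
#' @export
detect_spikes <- function(trace, threshold = 0, lockout_ms = 2, dt = NULL) {
  if (inherits(trace, "tspn_trace")) { v <- trace$v; dt <- trace$dt } else v <- trace
  stopifnot(!is.null(dt))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  if (!length(up)) return(numeric(0))
  keep <- up[1]
  for (i in up[-1]) if ((i - keep[length(keep)]) * dt >= lockout_ms) keep <- c(keep, i)
  keep * dt
}

# index of the sample nearest a given time
.t2i <- function(t_ms, dt, n) pmin(n, pmax(1, round(t_ms / dt)))

#' Fit passive membrane properties to a hyperpolarizing step response
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt, via
#' \code{minpack.lm::nlsLM}) of the charging curve
#' \eqn{V(t) = \Delta V e^{-t/\tau_m} + (V_{hold} - \Delta V)} over the step,
#' then \eqn{R_{in} = \Delta V / |I_{inj}|} and \eqn{C_m = \tau_m / R_{in}}.
#'
#' @param trace a \code{tspn_trace} containing a hyperpolarizing step.
#' @param window step on/off times in ms (default: trace metadata).
#' @param i_inj step current in pA (default: trace metadata); must be non-zero
#'   and the step at least 1.5 s for a reliable fit.
#' @return a \code{tspn_passive_fit}: list with \code{delta_v} (mV),
#'   \code{tau_m} (ms), \code{r_in} (MOhm), \code{c_m} (pF), \code{v_hold}
#'   (mV) and the fit residuals.
#' @export
fit_passive <- function(trace, window = trace$meta$window,
                        i_inj = trace$meta$step_pa) {
  if (is.null(window) || is.null(i_inj)) stop("need a step window and current")
  if (i_inj == 0) stop("i_inj must be non-zero")
  dt <- trace$dt
  n <- length(trace$v)
  i_on <- .t2i(window[1], dt, n); i_off <- .t2i(window[2], dt, n)
  v <- trace$v[(i_on + 1):i_off]
  t <- (seq_along(v) - 1) * dt
  v_hold <- mean(trace$v[.t2i(window[1] - 50, dt, n):i_on])
  dv0 <- v_hold - mean(v[t > max(t) * 0.9])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ dv * exp(-t / tau) + (vh - dv),
                      start = list(dv = dv0, tau = unname(diff(window)) / 10, vh = v_hold),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(errorCondition(
      paste("passive fit failed:", conditionMessage(e)),
      class = c("tspn_fit_error", "error", "condition"))))
  cf <- coef(fit)
  delta_v <- abs(unname(cf["dv"]))
  tau_m <- unname(cf["tau"])
  r_in <- 1000 * delta_v / abs(i_inj)      # mV/pA = GOhm -> MOhm
  structure(list(delta_v = delta_v, tau_m = tau_m, r_in = r_in,
                 c_m = 1000 * tau_m / r_in,  # ms / MOhm -> nF? see note: ms/GOhm = pF
                 v_hold = unname(cf["vh"]),
                 residuals = stats::residuals(fit), fitted = stats::fitted(fit)),
            class = "tspn_passive_fit")
}

#' @export
print.tspn_passive_fit <- function(x, ...) {
  cat(sprintf("passive fit: dV = %.2f mV, tau_m = %.1f ms, R_in = %.0f MOhm, C_m = %.1f pF\n",
              x$delta_v, x$tau_m, x$r_in, x$c_m))
  invisible(x)
}

#' @export
coef.tspn_passive_fit <- function(object, ...) {
  c(delta_v = object$delta_v, tau_m = object$tau_m, r_in = object$r_in,
    c_m = object$c_m, v_hold = object$v_hold)
}

#' @export
residuals.tspn_passive_fit <- function(object, ...) object$residuals

#' Action-potential threshold voltage
#'
#' Operationalizes "the point where dV/dt begins to increase" as the last
#' sample before the spike peak at which the voltage derivative crosses a
#' criterion (default 1 mV/ms) from below. The derivative is computed on a
#' lightly smoothed copy (5-sample moving average); the returned voltage is
#' read from the raw trace.
#'
#' @param trace a \code{tspn_trace}.
#' @param spike which spike to use (index into the detected spikes; default 1).
#' @param dvdt_criterion derivative criterion in mV/ms (default 1; suited to
#'   the slow rise of tSPN action potentials, and insensitive: doubling it
#'   moves the threshold by under 2 mV on model spikes).
#' @param spike_threshold detection threshold passed to
#'   \code{\link{detect_spikes}}.
#' @return list with \code{v_th} (mV), \code{t_th} (ms) and \code{index}.
#' @export
detect_threshold <- function(trace, spike = 1, dvdt_criterion = 1,
                             spike_threshold = 0) {
  sp <- detect_spikes(trace, threshold = spike_threshold)
  if (length(sp) < spike)
    stop(errorCondition("no such spike in trace",
                        class = c("tspn_detection_error", "error", "condition")))
  dt <- trace$dt
  n <- length(trace$v)
  i_sp <- .t2i(sp[spike], dt, n)
  # peak within 10 ms after the crossing
  i_pk <- i_sp + which.max(trace$v[i_sp:min(n, i_sp + round(10 / dt))]) - 1
  vs <- stats::filter(trace$v, rep(1 / 5, 5), sides = 2)
  vs[is.na(vs)] <- trace$v[is.na(vs)]
  dvdt <- c(0, diff(vs)) / dt
  # walk back from the point of maximal upstroke slope to the last
  # below-criterion sample
  i_lo <- max(2, i_sp - round(10 / dt))
  i_up <- i_lo + which.max(dvdt[i_lo:i_pk]) - 1
  i <- i_up
  while (i > 1 && dvdt[i] >= dvdt_criterion) i <- i - 1
  if (i == i_up || i <= 1)
    stop(errorCondition("dV/dt criterion never met before peak",
                        class = c("tspn_detection_error", "error", "condition")))
  list(v_th = trace$v[i + 1], t_th = (i + 1) * dt, index = i + 1)
}

#' Calculated rheobase from threshold, holding potential and input resistance
#'
#' \eqn{\hat I_{rheo} = (V_{th} - V_{hold}) / R_{in}}, reported in pA.
#'
#' @param v_th threshold voltage (mV).
#' @param v_hold holding voltage (mV).
#' @param r_in input resistance (MOhm, > 0).
#' @export
calculated_rheobase <- function(v_th, v_hold, r_in) {
  if (any(r_in <= 0)) stop("r_in must be positive")
  1000 * (v_th - v_hold) / r_in
}

#' Measured rheobase from an incremented step family
#'
#' The smallest step current that elicited exactly one spike; if the increment
#' jumps from zero spikes straight to several, the mean of the adjacent sub-
#' and suprathreshold currents (e.g. 0 spikes at 30 pA and several at 40 pA
#' gives 35 pA).
#'
#' @param step_pa increasing step currents (pA).
#' @param n_spikes spike counts per step.
#' @return rheobase estimate in pA.
#' @export
measured_rheobase_from_steps <- function(step_pa, n_spikes) {
  stopifnot(length(step_pa) == length(n_spikes), !is.unsorted(step_pa))
  first <- which(n_spikes >= 1)[1]
  if (is.na(first))
    stop(errorCondition("no spiking step",
                        class = c("tspn_not_excitable", "error", "condition")))
  if (n_spikes[first] == 1 || first == 1) return(step_pa[first])
  mean(step_pa[c(first - 1, first)])
}

#' Action-potential shape metrics
#'
#' Threshold (via \code{\link{detect_threshold}}), absolute peak, amplitude
#' (peak minus threshold), half-width (width at half amplitude, linearly
#' interpolated) and maximal rise slope between threshold and peak.
#'
#' @param trace a \code{tspn_trace}.
#' @param spike spike index (default 1).
#' @param ... passed to \code{\link{detect_threshold}}.
#' @return list with \code{v_threshold}, \code{peak}, \code{amplitude},
#'   \code{half_width}, \code{rise_slope}.
#' @export
ap_metrics <- function(trace, spike = 1, ...) {
  th <- detect_threshold(trace, spike = spike, ...)
  dt <- trace$dt
  n <- length(trace$v)
  i0 <- th$index
  i_pk <- i0 + which.max(trace$v[i0:min(n, i0 + round(15 / dt))]) - 1
  peak <- trace$v[i_pk]
  amp <- peak - th$v_th
  vhalf <- th$v_th + amp / 2
  # interpolated half-amplitude crossings around the peak
  iu <- i0 + which(trace$v[i0:i_pk] >= vhalf)[1] - 1
  t_up <- dt * (iu - 1 + (vhalf - trace$v[iu - 1]) / (trace$v[iu] - trace$v[iu - 1]))
  after <- trace$v[i_pk:min(n, i_pk + round(50 / dt))]
  idn <- i_pk + which(after <= vhalf)[1] - 1
  t_dn <- if (is.na(idn)) NA_real_ else
    dt * (idn - 1 + (trace$v[idn - 1] - vhalf) / (trace$v[idn - 1] - trace$v[idn]))
  rise <- max(diff(trace$v[i0:i_pk])) / dt
  list(v_threshold = th$v_th, peak = peak, amplitude = amp,
       half_width = t_dn - t_up, rise_slope = rise)
}

#' Fast afterhyperpolarization metrics
#'
#' Computed only when the minimal suprathreshold trace contains exactly one
#' spike (otherwise returns NULL, mirroring the per-cell availability of this
#' measure): amplitude = steady-state voltage during the step minus the peak
#' negative voltage after the spike; half-decay = time for the fAHP to decay to
#' half its amplitude; duration = time from spike onset (threshold crossing)
#' until the voltage returns to within \code{band} of the steady-state
#' baseline.
#'
#' @param trace a single-spike step response at minimal suprathreshold current.
#' @param window step window (ms).
#' @param band baseline tolerance (mV).
#' @return list with \code{amplitude}, \code{half_decay}, \code{duration}, or
#'   NULL when the single-spike precondition fails.
#' @export
fahp_metrics <- function(trace, window = trace$meta$window, band = 0.5) {
  sp <- detect_spikes(trace)
  sp <- sp[sp > window[1] & sp <= window[2]]
  if (length(sp) != 1) return(NULL)
  dt <- trace$dt
  n <- length(trace$v)
  th <- detect_threshold(trace)
  i_on <- th$index
  # steady-state voltage in the last 20% of the step
  i_w <- .t2i(window, dt, n)
  v_ss <- mean(trace$v[.t2i(window[2] - 0.2 * diff(window), dt, n):i_w[2]])
  seg <- trace$v[i_on:i_w[2]]
  i_min <- i_on + which.min(seg) - 1
  amp <- v_ss - trace$v[i_min]
  if (amp <= 0) return(NULL)
  rec <- trace$v[i_min:i_w[2]]
  ih <- which(rec >= v_ss - amp / 2)[1]
  half_decay <- if (is.na(ih)) NA_real_ else (ih - 1) * dt
  ib <- which(rec >= v_ss - band)[1]
  duration <- if (is.na(ib)) NA_real_ else (i_min - i_on + ib - 1) * dt
  list(amplitude = amp, half_decay = half_decay, duration = duration)
}

#' Slow afterhyperpolarization metrics
#'
#' Measured after the step offset (conventionally at the largest current
#' tested): amplitude = pre-step baseline (holding voltage) minus the peak
#' negative voltage after offset; half-decay = time to recover half the
#' amplitude.
#'
#' @param trace a step response with post-step samples.
#' @param window step window (ms).
#' @return list with \code{amplitude} and \code{half_decay}, or NULL when no
#'   undershoot below baseline occurs.
#' @export
sahp_metrics <- function(trace, window = trace$meta$window) {
  dt <- trace$dt
  n <- length(trace$v)
  i_w <- .t2i(window, dt, n)
  if (i_w[2] >= n - round(10 / dt)) stop("trace has no post-step samples")
  v_base <- mean(trace$v[.t2i(window[1] - 50, dt, n):i_w[1]])
  post <- trace$v[i_w[2]:n]
  i_min <- which.min(post)
  amp <- v_base - post[i_min]
  if (amp <= 0) return(NULL)
  rec <- post[i_min:length(post)]
  ih <- which(rec >= v_base - amp / 2)[1]
  list(amplitude = amp,
       half_decay = if (is.na(ih)) NA_real_ else (ih - 1) * dt)
}

#' Firing rates and spike-rate adaptation from spike times
#'
#' Instantaneous firing rate (IFR) is the inverse interspike interval. The
#' maximal rate is the IFR of the first spike pair after step onset; the
#' sustained rate is the mean IFR of the last three intervals, provided they
#' fall within the last half of the step; the SRA ratio is maximal/sustained.
#'
#' @param spike_times spike times in ms.
#' @param window step on/off times in ms.
#' @return list with \code{ifr} (data.frame of interval mid-times and rates),
#'   \code{max_rate}, \code{sustained_rate}, \code{sra_ratio} (Hz / ratio;
#'   NULL where undefined).
#' @export
firing_rates <- function(spike_times, window) {
  sp <- spike_times[spike_times > window[1] & spike_times <= window[2]]
  if (length(sp) < 2)
    return(list(ifr = NULL, max_rate = NULL, sustained_rate = NULL, sra_ratio = NULL))
  isi <- diff(sp)
  ifr <- data.frame(t = (sp[-1] + sp[-length(sp)]) / 2, rate = 1000 / isi)
  max_rate <- 1000 / isi[1]
  sustained <- NULL
  if (length(isi) >= 3) {
    last3 <- (length(isi) - 2):length(isi)
    half <- window[1] + diff(window) / 2
    # the three intervals qualify when the spikes closing them fall in the
    # last half of the step
    if (sp[length(sp) - 2] >= half) sustained <- mean(1000 / isi[last3])
  }
  list(ifr = ifr, max_rate = max_rate, sustained_rate = sustained,
       sra_ratio = if (is.null(sustained)) NULL else max_rate / sustained)
}

#' Detect a depolarizing sag during a hyperpolarizing step
#'
#' Sag = the steady-state voltage late in the step is depolarized relative to
#' the early minimum (the trough within the first half of the step) by more
#' than \code{criterion} (default 1 mV). A monotone exponential response has
#' its minimum at the end of the step and therefore never flags.
#'
#' @param trace a hyperpolarizing step response.
#' @param window step window (ms).
#' @param criterion sag amplitude criterion (mV).
#' @return list with \code{sag} (logical) and \code{amplitude} (mV).
#' @export
detect_sag <- function(trace, window = trace$meta$window, criterion = 1) {
  dt <- trace$dt
  n <- length(trace$v)
  i_w <- .t2i(window, dt, n)
  v_hold <- mean(trace$v[.t2i(window[1] - 50, dt, n):i_w[1]])
  seg <- trace$v[i_w[1]:i_w[2]]
  if (min(seg) >= v_hold)
    stop(errorCondition("not a hyperpolarizing response",
                        class = c("tspn_detection_error", "error", "condition")))
  v_min <- min(seg[seq_len(ceiling(length(seg) / 2))])
  v_ss <- mean(seg[seq(round(0.8 * length(seg)), length(seg))])
  amp <- v_ss - v_min
  list(sag = amp > criterion, amplitude = amp)
}

#' Detect rebound firing after a hyperpolarizing step
#'
#' @param trace a step response including post-step samples.
#' @param window step window (ms).
#' @param rebound_window_ms window after step offset to look for a spike.
#' @return logical.
#' @export
detect_rebound <- function(trace, window = trace$meta$window,
                           rebound_window_ms = 500) {
  sp <- detect_spikes(trace)
  any(sp > window[2] & sp <= window[2] + rebound_window_ms)
}

#' Detect a pre-spike notch on a depolarizing step
#'
#' A notch is a hyperpolarizing deflection of the charging trajectory from its
#' exponential course before the first spike (classically caused by
#' de-inactivated A-type current): a single exponential is fitted to the
#' pre-spike segment and the notch depth is the maximal deviation of the
#' voltage below that fit. Flags a notch when the depth exceeds
#' \code{criterion} (default 1 mV).
#'
#' @param trace a depolarizing step response.
#' @param window step window (ms).
#' @param criterion deflection criterion (mV).
#' @return list with \code{notch} (logical) and \code{depth} (mV).
#' @export
detect_notch <- function(trace, window = trace$meta$window, criterion = 1) {
  dt <- trace$dt
  n <- length(trace$v)
  i_w <- .t2i(window, dt, n)
  seg <- trace$v[i_w[1]:i_w[2]]
  if (max(seg) <= trace$v[i_w[1]])
    stop(errorCondition("not a depolarizing response",
                        class = c("tspn_detection_error", "error", "condition")))
  sp <- detect_spikes(trace)
  sp <- sp[sp > window[1] & sp <= window[2]]
  i_end <- if (length(sp)) {
    th <- detect_threshold(trace)
    max(10, th$index - i_w[1])
  } else length(seg)
  seg <- seg[1:i_end]
  t <- (seq_along(seg) - 1) * dt
  v0 <- seg[1]
  vss0 <- max(seg)
  fit <- tryCatch(
    minpack.lm::nlsLM(seg ~ vss + (v0f - vss) * exp(-t / tau),
                      start = list(vss = vss0, v0f = v0, tau = max(t) / 3),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(notch = FALSE, depth = 0))
  depth <- max(stats::fitted(fit) - seg)
  list(notch = depth > criterion, depth = depth)
}

#' Ultra-slow AHP flag
#'
#' Flags progressive baseline hyperpolarization across a family of repeated
#' depolarizing steps, with the membrane driven below the K+ equilibrium
#' potential. Detection only; no pump mechanism is modelled.
#'
#' @param baselines inter-step baseline voltages (mV), in protocol order.
#' @param e_k potassium equilibrium potential (mV).
#' @param drift_mv required total hyperpolarizing drift (mV).
#' @return logical.
#' @export
usahp_flag <- function(baselines, e_k = -98, drift_mv = 5) {
  if (length(baselines) < 3) return(FALSE)
  drift <- baselines[1] - baselines[length(baselines)]
  drift > drift_mv && min(baselines) < e_k
}

#' Liquid-junction-potential correction
#'
#' Subtracts 10 mV from absolute voltages (resting potential, absolute
#' threshold, peak voltage). Relative quantities (amplitudes, deflections) are
#' never corrected since the offset cancels in differences.
#'
#' @param values absolute voltages (mV).
#' @param correction correction to add (mV, default -10).
#' @export
ljp_correct <- function(values, correction = -10) values + correction
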