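# Virtual-experiment protocols: bias-current holding, rheobase binary search,
# strength-duration curves, f-I curves, firing-type classification and the
# impalement phase diagrams. All searches are deterministic given the model
# parameters and tolerances.

.settled_v <- function(params, bias, v_start, settle_ms, dt) {
  tr <- tspn_integrate(params, rep(bias, round(settle_ms / dt)),
                       init = steady_state_init(params, v_start), dt = dt)
  mean(tr$v[max(1, length(tr$v) - round(5 / dt)):length(tr$v)])
}

#' Bias current holding a cell at a target potential
#'
#' Finds, by bisection on constant current, the bias that leaves the settled
#' membrane potential within \code{tol} of \code{v_target}. The bracket is
#' seeded with the analytic steady-state current sum at \code{v_target} and
#' widened if needed; a bracket with no sign change raises an error.
#'
#' @param params a \code{tspn_neuron}.
#' @param v_target target holding potential in mV.
#' @param tol tolerance on the settled potential (mV, default 0.1).
#' @param settle_ms settling time per evaluation (ms).
#' @param dt time step (ms).
#' @return bias current in pA.
#' @export
find_bias_current <- function(params, v_target, tol = 0.1, settle_ms = 2000, dt = 0.1) {
  ss_current <- function(v) {
    st <- steady_state_init(params, v)
    sum(vapply(params$channels, channel_current, numeric(1), state = st))
  }
  i_guess <- ss_current(v_target)
  # bracket width scaled to the local slope conductance so the voltage
  # excursion stays bounded even for near-gigaohm cells
  g_slope <- max(0.05, (ss_current(v_target + 1) - ss_current(v_target - 1)) / 2)
  margin <- max(1, 5 * g_slope)
  f <- function(i) {
    v <- tryCatch(.settled_v(params, i, v_target, settle_ms, dt),
                  error = function(e) if (i < i_guess) -Inf else Inf)
    v - v_target
  }
  lo <- i_guess - margin; hi <- i_guess + margin
  k <- 0
  while (f(lo) > 0 && k < 6) { lo <- lo - 20 * margin; k <- k + 1 }
  k <- 0
  while (f(hi) < 0 && k < 6) { hi <- hi + 20 * margin; k <- k + 1 }
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop(errorCondition("could not bracket the bias current",
                        class = c("tspn_bracketing_error", "error", "condition")))
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-3) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
}

#' Hold a cell and apply a square current step
#'
#' Holds the cell at \code{hold_v} (via the given or a freshly solved bias
#' current), applies a square step of \code{step_pa} and returns the trace with
#' the step window in its metadata. The workhorse behind the rheobase, f-I and
#' phase-diagram protocols.
#'
#' @param params a \code{tspn_neuron}.
#' @param step_pa step amplitude (pA, on top of the bias).
#' @param hold_v holding potential (mV).
#' @param step_ms step duration (ms).
#' @param bias optional precomputed bias current (pA).
#' @param settle_ms pre-step settling time (ms).
#' @param post_ms post-step time (ms).
#' @param dt time step (ms).
#' @param ... passed to \code{\link{tspn_integrate}}.
#' @return a \code{tspn_trace}.
#' @export
run_step <- function(params, step_pa, hold_v = -70, step_ms = 1500, bias = NULL,
                     settle_ms = 500, post_ms = 0, dt = 0.1, ...) {
  if (is.null(bias)) bias <- find_bias_current(params, hold_v, dt = dt)
  stim <- step_stimulus(bias, step_pa, settle_ms = settle_ms, step_ms = step_ms,
                        post_ms = post_ms, dt = dt)
  stim$meta$hold_v <- hold_v
  tspn_integrate(params, stim$i_inj, init = steady_state_init(params, hold_v),
                 dt = dt, meta = stim$meta, ...)
}

#' Classify the firing type of a step response
#'
#' Non-firing (N): no spikes during the step. Phasic (P): at least one spike,
#' all confined to the first half of the step. Repetitive (R): at least one
#' spike in the final half of the step. Spikes are upward crossings of
#' \code{threshold} with a 2 ms lockout.
#'
#' @param trace a \code{tspn_trace} from a single-step protocol.
#' @param window step on/off times in ms (default: from the trace metadata).
#' @param threshold spike detection threshold (mV).
#' @return one of \code{"N"}, \code{"P"}, \code{"R"}.
#' @export
classify_firing <- function(trace, window = trace$meta$window, threshold = 0) {
  if (is.null(window)) stop("no step window available")
  sp <- detect_spikes(trace, threshold = threshold)
  sp <- sp[sp > window[1] & sp <= window[2]]
  if (length(sp) == 0) return("N")
  half <- window[1] + diff(window) / 2
  if (any(sp > half)) "R" else "P"
}

# Binary search for the minimal step current eliciting >= 1 spike.
.threshold_current <- function(params, hold_v, step_ms, tol, i_max, dt, bias) {
  fires <- function(i) {
    tr <- run_step(params, i, hold_v, step_ms, bias = bias, dt = dt)
    sp <- detect_spikes(tr)
    any(sp > tr$meta$window[1] & sp <= tr$meta$window[2])
  }
  if (!fires(i_max))
    stop(errorCondition(sprintf("no spike at i_max = %g pA", i_max),
                        class = c("tspn_not_excitable", "error", "condition")))
  lo <- 0; hi <- i_max
  if (fires(0)) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Measured rheobase by binary search
#'
#' Minimal long-duration current step (default 1.5 s) that elicits at least one
#' spike, found by binary search on [0, \code{i_max}] to within \code{tol}
#' (default 0.5 pA), with the cell held at \code{hold_v} by a bias current. A
#' cell that does not spike at \code{i_max} (e.g. with the Na conductance
#' removed) raises a \code{tspn_not_excitable} error.
#'
#' @param params a \code{tspn_neuron}.
#' @param hold_v holding potential (mV).
#' @param step_dur step duration in ms (>= 1500).
#' @param tol search tolerance in pA.
#' @param i_max search ceiling in pA.
#' @param dt time step (ms).
#' @param bias optional precomputed bias current (pA).
#' @return rheobase in pA.
#' @export
measure_rheobase <- function(params, hold_v = -70, step_dur = 1500, tol = 0.5,
                             i_max = 600, dt = 0.1, bias = NULL) {
  stopifnot(step_dur >= 1500)
  if (is.null(bias)) bias <- find_bias_current(params, hold_v, dt = dt)
  .threshold_current(params, hold_v, step_dur, tol, i_max, dt, bias)
}

#' Strength-duration curve
#'
#' Minimal spiking current as a function of step duration (same search as
#' \code{\link{measure_rheobase}}, without the long-duration restriction).
#' The curve is monotone non-increasing in duration; its long-duration
#' asymptote is the rheobase.
#'
#' @param params a \code{tspn_neuron}.
#' @param durations step durations in ms, sorted, positive.
#' @param hold_v holding potential (mV).
#' @param tol search tolerance (pA).
#' @param i_max search ceiling (pA); short pulses need large currents.
#' @param dt time step (ms).
#' @return data.frame with \code{duration_ms}, \code{threshold_pa};
#'   class \code{tspn_sd_curve}.
#' @export
strength_duration <- function(params, durations, hold_v = -70, tol = 0.5,
                              i_max = 5000, dt = 0.1) {
  stopifnot(all(durations > 0), !is.unsorted(durations))
  bias <- find_bias_current(params, hold_v, dt = dt)
  th <- vapply(durations, function(d)
    .threshold_current(params, hold_v, d, tol, i_max, dt, bias), numeric(1))
  structure(data.frame(duration_ms = durations, threshold_pa = th),
            class = c("tspn_sd_curve", "data.frame"))
}

#' @export
plot.tspn_sd_curve <- function(x, ...) {
  plot(x$duration_ms, x$threshold_pa, type = "b", log = "xy",
       xlab = "step duration (ms)", ylab = "threshold current (pA)", ...)
  invisible(x)
}

#' Frequency-current (f-I) curve
#'
#' For each injected current: maximal rate = inverse of the first interspike
#' interval at step onset; sustained rate = mean instantaneous rate of the last
#' three interspike intervals, provided they fall in the last half of the step
#' (absent otherwise). Slopes are least-squares fits over the defined points.
#'
#' @param params a \code{tspn_neuron}.
#' @param currents sorted injected-current values (pA).
#' @param hold_v holding potential (mV).
#' @param step_dur step duration in ms (>= 1500; 3 s default).
#' @param dt time step (ms).
#' @param bias optional precomputed bias current.
#' @return a \code{tspn_fi_curve}: data.frame with \code{current_pa},
#'   \code{max_rate}, \code{sustained_rate} (Hz, NA where undefined) plus
#'   attributes \code{max_slope} and \code{sustained_slope} (Hz/pA).
#' @export
fi_curve <- function(params, currents, hold_v = -70, step_dur = 3000, dt = 0.1,
                     bias = NULL) {
  stopifnot(!is.unsorted(currents))
  if (is.null(bias)) bias <- find_bias_current(params, hold_v, dt = dt)
  rows <- lapply(currents, function(i) {
    tr <- run_step(params, i, hold_v, step_dur, bias = bias, dt = dt)
    fr <- firing_rates(detect_spikes(tr), tr$meta$window)
    data.frame(current_pa = i,
               max_rate = if (is.null(fr$max_rate)) NA_real_ else fr$max_rate,
               sustained_rate = if (is.null(fr$sustained_rate)) NA_real_ else fr$sustained_rate)
  })
  out <- do.call(rbind, rows)
  slope <- function(y) if (sum(!is.na(y)) >= 2)
    unname(coef(lm(y ~ out$current_pa))[2]) else NA_real_
  structure(out, max_slope = slope(out$max_rate),
            sustained_slope = slope(out$sustained_rate),
            class = c("tspn_fi_curve", "data.frame"))
}

#' @export
plot.tspn_fi_curve <- function(x, ...) {
  plot(x$current_pa, x$max_rate, type = "b", pch = 16,
       xlab = "injected current (pA)", ylab = "firing rate (Hz)",
       ylim = range(0, x$max_rate, na.rm = TRUE), ...)
  graphics::lines(x$current_pa, x$sustained_rate, type = "b", pch = 1, lty = 2)
  graphics::legend("topleft", c("maximal", "sustained"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Firing-type phase boundaries in the (g_imp, current) plane
#'
#' For each impalement conductance, the cell is held at \code{hold_v} via a
#' bias current and the boundary currents between non-firing (N), phasic (P)
#' and repetitive (R) responses to long current steps are located by binary
#' search to within \code{tol}. Boundaries are NA where a region is empty
#' (e.g. the P region vanishes when the M conductance is removed).
#'
#' @param params a \code{tspn_neuron} (the impalement channel's conductance is
#'   overridden per grid value).
#' @param g_imp_values impalement conductances to scan (nS).
#' @param i_max largest current considered (pA, default 600).
#' @param tol boundary tolerance (pA).
#' @param hold_v holding potential (mV).
#' @param step_dur step duration (ms).
#' @param dt time step (ms).
#' @return a \code{tspn_phase_diagram}: data.frame with columns \code{g_imp},
#'   \code{n_to_p}, \code{n_to_r}, \code{p_to_r} (pA).
#' @export
phase_boundaries <- function(params, g_imp_values, i_max = 600, tol = 0.5,
                             hold_v = -70, step_dur = 3000, dt = 0.1) {
  rows <- lapply(g_imp_values, function(gi) {
    p2 <- params
    p2$channels$imp$g_max <- gi
    bias <- find_bias_current(p2, hold_v, dt = dt)
    cls <- function(i) {
      tr <- run_step(p2, i, hold_v, step_dur, bias = bias, dt = dt)
      classify_firing(tr)
    }
    n_to_p <- n_to_r <- p_to_r <- NA_real_
    if (cls(i_max) != "N") {
      lo <- 0; hi <- i_max
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (cls(mid) == "N") lo <- mid else hi <- mid
      }
      onset <- (lo + hi) / 2
      above <- cls(hi)
      if (above == "R") {
        n_to_r <- onset
      } else {
        n_to_p <- onset
        # look for a repetitive window above the phasic region (the class
        # sequence need not be monotone: a grid scan locates the first R,
        # then a binary search refines the P-to-R boundary)
        grid <- seq(hi, i_max, length.out = 9)[-1]
        r_at <- grid[which(vapply(grid, function(i) cls(i) == "R", logical(1)))[1]]
        if (!is.na(r_at)) {
          lo2 <- hi; hi2 <- r_at
          while (hi2 - lo2 > tol) {
            mid <- (lo2 + hi2) / 2
            if (cls(mid) == "R") hi2 <- mid else lo2 <- mid
          }
          p_to_r <- (lo2 + hi2) / 2
        }
      }
    }
    data.frame(g_imp = gi, n_to_p = n_to_p, n_to_r = n_to_r, p_to_r = p_to_r)
  })
  structure(do.call(rbind, rows), tol = tol, i_max = i_max,
            class = c("tspn_phase_diagram", "data.frame"))
}

#' @export
plot.tspn_phase_diagram <- function(x, ...) {
  ymax <- attr(x, "i_max")
  plot(NA, xlim = range(x$g_imp), ylim = c(0, ymax),
       xlab = "g_imp (nS)", ylab = "injected current (pA)", ...)
  onset <- ifelse(is.na(x$n_to_r), x$n_to_p, x$n_to_r)
  graphics::lines(x$g_imp, onset, type = "b", pch = 16)
  if (any(!is.na(x$p_to_r)))
    graphics::lines(x$g_imp, x$p_to_r, type = "b", pch = 1, lty = 2)
  graphics::legend("topleft", c("firing onset (N boundary)", "P to R boundary"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Input resistance of a model cell
#'
#' Steady-state voltage deflection per unit current for a small hyperpolarizing
#' probe with the cell held at \code{hold_v} via bias current.
#'
#' @param params a \code{tspn_neuron}.
#' @param hold_v holding potential (mV).
#' @param probe_pa probe current (pA; small and hyperpolarizing by default).
#' @param probe_ms probe duration (ms).
#' @param dt time step (ms).
#' @param bias optional precomputed bias current.
#' @return input resistance in MOhm.
#' @export
model_input_resistance <- function(params, hold_v = -70, probe_pa = -10,
                                   probe_ms = 1500, dt = 0.1, bias = NULL) {
  if (is.null(bias)) bias <- find_bias_current(params, hold_v, dt = dt)
  tr <- run_step(params, probe_pa, hold_v, probe_ms, bias = bias,
                 settle_ms = 500, dt = dt)
  t <- trace_time(tr)
  w <- tr$meta$window
  v_hold <- mean(tr$v[t > w[1] - 50 & t <= w[1]])
  v_ss <- mean(tr$v[t > w[2] - 100 & t <= w[2]])
  1000 * (v_ss - v_hold) / probe_pa
}
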