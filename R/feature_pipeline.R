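# Per-cell feature pipeline: runs the standard current-step battery on a model
# cell and extracts the full feature set, mirroring how recorded cells are
# characterized from a single family of steps.

#' Extract the electrophysiological feature set of a model cell
#'
#' Runs the characterization battery: a hyperpolarizing step (scaled to
#' roughly -5 mV deflection) for the passive fit; an incremented family of
#' depolarizing steps for measured rheobase; AP/threshold metrics at minimal
#' suprathreshold current; fAHP (single-spike traces only); firing rates and
#' the SRA ratio at twice the minimal suprathreshold current; f-I slopes over
#' a multiple-of-rheobase current ladder; sAHP after the largest step.
#'
#' @param params a \code{tspn_neuron}.
#' @param hold_v holding potential (mV).
#' @param step_dur step duration (ms).
#' @param increment_pa increment of the rheobase step family (pA).
#' @param i_max largest current attempted (pA).
#' @param dt time step (ms).
#' @return one-row data.frame (feature set); unavailable features are NA.
#' @export
extract_features <- function(params, hold_v = -70, step_dur = 1500,
                             increment_pa = 5, i_max = 600, dt = 0.1) {
  bias <- find_bias_current(params, hold_v, dt = dt)

  # passive properties from a hyperpolarizing step scaled to ~ -5 mV
  r0 <- model_input_resistance(params, hold_v, probe_pa = -5, dt = dt, bias = bias)
  probe <- max(-50, min(-1, -5000 / r0))
  tr_pass <- run_step(params, probe, hold_v, max(step_dur, 1500), bias = bias, dt = dt)
  pf <- fit_passive(tr_pass)

  # incremented step family for measured rheobase
  steps <- seq(increment_pa, i_max, by = increment_pa)
  counts <- integer(0)
  traces <- list()
  for (i in seq_along(steps)) {
    tr <- run_step(params, steps[i], hold_v, step_dur, bias = bias, dt = dt,
                   post_ms = 1500)
    sp <- detect_spikes(tr)
    counts[i] <- sum(sp > tr$meta$window[1] & sp <= tr$meta$window[2])
    traces[[i]] <- tr
    if (sum(counts >= 1) >= 1 && steps[i] >= 2 * steps[which(counts >= 1)[1]]) break
  }
  first <- which(counts >= 1)[1]
  if (is.na(first))
    stop(errorCondition("cell not excitable within i_max",
                        class = c("tspn_not_excitable", "error", "condition")))
  rheo_meas <- measured_rheobase_from_steps(steps[seq_along(counts)], counts)
  tr_min <- traces[[first]]                     # minimal suprathreshold trace

  ap <- ap_metrics(tr_min)
  rheo_calc <- calculated_rheobase(ap$v_threshold, hold_v, pf$r_in)
  fahp <- fahp_metrics(tr_min)

  # rates at twice minimal suprathreshold current
  i2 <- which(steps[seq_along(counts)] >= 2 * steps[first])[1]
  tr2 <- if (!is.na(i2)) traces[[i2]] else
    run_step(params, 2 * steps[first], hold_v, step_dur, bias = bias, dt = dt,
             post_ms = 1500)
  fr2 <- firing_rates(detect_spikes(tr2), tr2$meta$window)
  sahp <- sahp_metrics(tr2)

  fi <- fi_curve(params, steps[first] * c(1.5, 2, 3, 4), hold_v,
                 step_dur = max(step_dur, 1500), dt = dt, bias = bias)

  na_if_null <- function(x) if (is.null(x)) NA_real_ else x
  data.frame(
    r_in = pf$r_in, tau_m = pf$tau_m, c_m = pf$c_m, v_hold = hold_v,
    rheobase_measured = rheo_meas, rheobase_calculated = rheo_calc,
    v_threshold = ap$v_threshold, v_threshold_rel = ap$v_threshold - hold_v,
    ap_amplitude = ap$amplitude, ap_peak = ap$peak,
    ap_half_width = ap$half_width, ap_rise_slope = ap$rise_slope,
    fahp_amplitude = na_if_null(fahp$amplitude),
    fahp_half_decay = na_if_null(fahp$half_decay),
    fahp_duration = na_if_null(fahp$duration),
    sahp_amplitude = na_if_null(sahp$amplitude),
    sahp_half_decay = na_if_null(sahp$half_decay),
    max_rate_2x = na_if_null(fr2$max_rate),
    sustained_rate_2x = na_if_null(fr2$sustained_rate),
    sra_ratio = na_if_null(fr2$sra_ratio),
    fi_slope_max = attr(fi, "max_slope"),
    fi_slope_sustained = attr(fi, "sustained_slope"))
}
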