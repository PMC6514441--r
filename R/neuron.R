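#' Construct a tSPN model neuron
#'
#' Builds the single-compartment conductance-based model of a thoracic
#' sympathetic postganglionic neuron (tSPN). The membrane carries nine currents
#' (fast Na, delayed-rectifier Kd, slow non-inactivating M, calcium-dependent
#' KCa, fast transient A, hyperpolarization-activated H, persistent CaL, an
#' ohmic leak and an ohmic impalement-injury leak) obeying
#' \deqn{C_m dV/dt = -\sum_i G_i m^p h^q (V - E_i) + I_{inj},}
#' with first-order gating kinetics and a single intracellular calcium pool
#' \deqn{d[Ca]/dt = \lambda(-\alpha I_{CaL} - k_{CaS} [Ca]).}
#'
#' The default maximal conductances and reversal potentials are the standard
#' model cell (in nS / mV): Na 300/60, CaL 1.2/120, Kd 2000/-90, M 50/-90,
#' KCa 50/-90, A 50/-90, H 1/-32, leak 1/-55, imp 0/-15. Named presets encode
#' the per-experiment variants used in the virtual experiments (see
#' \code{tspn_presets()}).
#'
#' @param preset name of a parameter preset; see \code{tspn_presets()}.
#' @param g named numeric vector of maximal-conductance overrides in nS,
#'   e.g. \code{c(M = 30, leak = 2, imp = 7)}.
#' @param e_rev named numeric vector of reversal-potential overrides in mV.
#' @param c_m membrane capacitance in pF (default 100).
#' @param calcium list with \code{lambda} (free-to-bound ratio, default 0.01),
#'   \code{alpha} (uM ms^-1 pA^-1, default 0.002) and \code{k_removal}
#'   (ms^-1, default 0.024).
#' @param kinetics a kinetics configuration name or object; see
#'   \code{\link{tspn_kinetics}}.
#' @return an object of class \code{tspn_neuron}: a list with fields
#'   \code{c_m}, \code{channels} (named list of channel specifications) and
#'   \code{calcium}.
#' @examples
#' cell <- tspn_neuron()                       # standard model cell
#' impaled <- tspn_neuron(g = c(imp = 7))      # with impalement shunt
#' coef(cell)
#' @export
tspn_neuron <- function(preset = "standard", g = NULL, e_rev = NULL, c_m = 100,
                        calcium = list(lambda = 0.01, alpha = 0.002, k_removal = 0.024),
                        kinetics = "standard") {
  if (is.character(kinetics)) kinetics <- tspn_kinetics(kinetics)
  base_g <- c(Na = 300, CaL = 1.2, Kd = 2000, M = 50, KCa = 50, A = 50,
              H = 1, leak = 1, imp = 0)
  base_e <- c(Na = 60, CaL = 120, Kd = -90, M = -90, KCa = -90, A = -90,
              H = -32, leak = -55, imp = -15)
  pg <- tspn_presets()[[preset]]
  if (is.null(pg)) stop("unknown preset: ", preset)
  base_g[names(pg)] <- pg
  if (!is.null(g)) {
    bad <- setdiff(names(g), names(base_g))
    if (length(bad)) stop("unknown channel name(s): ", paste(bad, collapse = ", "))
    base_g[names(g)] <- g
  }
  if (!is.null(e_rev)) {
    bad <- setdiff(names(e_rev), names(base_e))
    if (length(bad)) stop("unknown channel name(s): ", paste(bad, collapse = ", "))
    base_e[names(e_rev)] <- e_rev
  }
  if (any(base_g < 0)) stop("maximal conductances must be >= 0")
  if (!is.numeric(c_m) || length(c_m) != 1L || c_m <= 0) stop("c_m must be a positive scalar")
  calcium <- modifyList(list(lambda = 0.01, alpha = 0.002, k_removal = 0.024), calcium)
  if (any(unlist(calcium) <= 0)) stop("calcium parameters must be strictly positive")

  channels <- lapply(names(base_g), function(nm) {
    kin <- kinetics$channels[[nm]]
    list(name = nm,
         g_max = unname(base_g[[nm]]),
         e_rev = unname(base_e[[nm]]),
         p = if (is.null(kin$p)) 0L else as.integer(kin$p),
         q = if (is.null(kin$q)) 0L else as.integer(kin$q),
         activation = kin$activation,
         inactivation = kin$inactivation,
         calcium_gate = kin$calcium,
         calcium_dependent = !is.null(kin$calcium),
         is_ca_source = identical(nm, "CaL"))
  })
  names(channels) <- names(base_g)

  structure(list(c_m = c_m, channels = channels, calcium = calcium,
                 kinetics_name = kinetics$name, preset = preset),
            class = "tspn_neuron")
}

#' Named parameter presets for the virtual experiments
#'
#' Each preset records the maximal-conductance overrides (relative to the
#' standard model cell) used for a particular reproduction: \code{fig3b}
#' (rheobase vs input conductance: M 20, A 15), \code{fig3c} (strength-duration
#' curves: standard cell), \code{fig4} (repetitive firing / f-I: M 30, KCa 70,
#' A 80, leak 2), \code{fig5} (firing-type phase diagrams: leak 0.5),
#' \code{fig6} (spike-rate adaptation: Na 400, Kd 3000, M 40, KCa 60, A 80,
#' leak 2), \code{fig8a} (notch: M 10, KCa 10, A 90, leak 0), \code{fig8b}
#' (sag: A 5, leak 0.1), \code{fig8c} (rebound: Na 200, Kd 2000, M 20, KCa 20,
#' A 20, leak 2).
#'
#' @return named list of named numeric conductance-override vectors (nS).
#' @export
tspn_presets <- function() {
  list(standard = numeric(0),
       fig3b = c(M = 20, A = 15),
       fig3c = numeric(0),
       fig4  = c(M = 30, KCa = 70, A = 80, leak = 2),
       fig5  = c(leak = 0.5),
       fig6  = c(Na = 400, Kd = 3000, CaL = 1.2, M = 40, KCa = 60, A = 80, H = 1, leak = 2),
       fig8a = c(M = 10, KCa = 10, A = 90, leak = 0),
       fig8b = c(A = 5, leak = 0.1),
       fig8c = c(Na = 200, Kd = 2000, CaL = 1.2, M = 20, KCa = 20, A = 20, H = 1, leak = 2))
}

#' Remove channels from a model cell
#'
#' Returns a copy of the cell with the named maximal conductances set to zero
#' (a simulated pharmacological block / genetic knockout). Knockouts commute:
#' the order channels are removed in does not matter.
#'
#' @param params a \code{tspn_neuron}.
#' @param channels character vector of channel names, e.g. \code{c("M", "KCa")}.
#' @export
knockout <- function(params, channels) {
  stopifnot(inherits(params, "tspn_neuron"))
  bad <- setdiff(channels, names(params$channels))
  if (length(bad)) stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  for (nm in channels) params$channels[[nm]]$g_max <- 0
  params
}

#' @export
coef.tspn_neuron <- function(object, ...) {
  vapply(object$channels, function(ch) ch$g_max, numeric(1))
}

#' @export
print.tspn_neuron <- function(x, ...) {
  cat("tSPN model neuron (preset '", x$preset, "', kinetics '", x$kinetics_name,
      "')\n", sep = "")
  cat("  C_m:", x$c_m, "pF\n")
  g <- coef(x)
  e <- vapply(x$channels, function(ch) ch$e_rev, numeric(1))
  cat("  conductances (nS):",
      paste(sprintf("%s=%g", names(g), g), collapse = ", "), "\n")
  cat("  reversals (mV):   ",
      paste(sprintf("%s=%g", names(e), e), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tspn_neuron <- function(object, hold_v = -70, ...) {
  rin <- model_input_resistance(object, hold_v = hold_v)
  st <- steady_state_init(object, hold_v)
  out <- list(params = object, hold_v = hold_v, r_in = rin,
              # MOhm * pF = us; express in ms
              tau_m = rin * object$c_m * 1e-3,
              ca_rest = st$ca)
  class(out) <- "summary.tspn_neuron"
  out
}

#' @export
print.summary.tspn_neuron <- function(x, ...) {
  print(x$params)
  cat(sprintf("  at %g mV hold: R_in = %.0f MOhm, nominal tau_m = %.1f ms, rest [Ca] = %.4f uM\n",
              x$hold_v, x$r_in, x$tau_m, x$ca_rest))
  invisible(x)
}
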