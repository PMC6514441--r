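#' @useDynLib tspn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef lm median pt quantile rlnorm rnorm rpois runif sd setNames simulate uniroot var
#' @importFrom utils modifyList read.table write.table
NULL

.tspn_env <- new.env(parent = emptyenv())

#' Gating kinetics configurations
#'
#' Gating kinetics are data, not code: every voltage-dependent steady state is a
#' Boltzmann curve and every voltage-dependent time constant a bell-shaped
#' function, with the numerical parameters stored in a versioned YAML file under
#' \code{inst/extdata}. \code{tspn_kinetics()} loads (and caches) such a
#' configuration. The calcium-gated KCa activation is a Hill function of the
#' intracellular calcium concentration with a fixed time constant.
#'
#' @param name name of a shipped configuration (currently \code{"standard"}) or
#'   a path to a YAML file with the same layout.
#' @return a list with elements \code{version}, \code{name} and \code{channels};
#'   each channel holds integer exponents \code{p}, \code{q} and parameter lists
#'   \code{activation}/\code{inactivation}/\code{calcium} as applicable.
#' @export
tspn_kinetics <- function(name = "standard") {
  key <- paste0("kinetics_", name)
  if (!is.null(.tspn_env[[key]])) return(.tspn_env[[key]])
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("kinetics_", name, ".yaml"), package = "tspn")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown kinetics configuration: ", name)
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$channels))
  .tspn_env[[key]] <- cfg
  cfg
}

# Boltzmann steady state; k < 0 yields a curve falling with depolarization.
gate_inf <- function(v, gate) 1 / (1 + exp((gate$vhalf - v) / gate$k))

# Bell-shaped voltage-dependent time constant (strictly positive by construction
# as long as tau_min > 0 or tau_amp > 0).
gate_tau <- function(v, gate) {
  gate$tau_min + gate$tau_amp /
    (exp((v - gate$tau_vhalf) / gate$tau_k1) + exp(-(v - gate$tau_vhalf) / gate$tau_k2))
}

# Hill-type calcium dependence of the KCa activation gate.
ca_gate_inf <- function(ca, gate) ca^gate$hill / (ca^gate$hill + gate$kd^gate$hill)
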