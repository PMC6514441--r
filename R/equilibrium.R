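# Physical constants (CODATA): R in J/(mol K), F in C/mol.
.R_GAS <- 8.314462618
.F_FARADAY <- 96485.33212

#' Nernst equilibrium potential
#'
#' @param valence ion valence (non-zero integer, e.g. +1 for K+).
#' @param conc_in,conc_out intracellular / extracellular concentrations in mM.
#' @param temperature absolute temperature in K; default 295 K (room
#'   temperature, matching the recording conditions).
#' @return equilibrium potential in mV.
#' @examples
#' nernst(1, 140, 3.10)  # K+ with a K-gluconate pipette against ACSF: ~ -97 mV
#' @export
nernst <- function(valence, conc_in, conc_out, temperature = 295) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be strictly positive")
  if (valence == 0) stop("valence must be non-zero")
  1000 * .R_GAS * temperature / (valence * .F_FARADAY) * log(conc_out / conc_in)
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Multi-ion reversal potential for Na+, K+ and Cl- with relative permeabilities
#' \code{perm}; the chloride concentrations enter with inside and outside
#' swapped, as usual for an anion. With equal permeabilities and the recording
#' solutions of \code{\link{tspn_solutions}} this evaluates to about -14 mV,
#' the basis for the -15 mV reversal of the impalement-injury leak.
#'
#' @param perm named numeric vector \code{c(Na = , K = , Cl = )} of relative
#'   permeabilities (non-negative, not all zero).
#' @param conc_in,conc_out named numeric vectors of concentrations (mM) for
#'   \code{Na}, \code{K}, \code{Cl}.
#' @param temperature absolute temperature in K (default 295).
#' @return reversal potential in mV.
#' @examples
#' sol <- tspn_solutions()
#' ghk_reversal(c(Na = 1, K = 1, Cl = 1), sol$pipette, sol$acsf)
#' @export
ghk_reversal <- function(perm, conc_in, conc_out, temperature = 295) {
  ions <- c("Na", "K", "Cl")
  for (x in list(perm, conc_in, conc_out))
    if (!all(ions %in% names(x))) stop("perm/conc vectors must name Na, K and Cl")
  if (any(perm < 0) || all(perm == 0)) stop("permeabilities must be >= 0 and not all zero")
  num <- perm[["Na"]] * conc_out[["Na"]] + perm[["K"]] * conc_out[["K"]] +
    perm[["Cl"]] * conc_in[["Cl"]]
  den <- perm[["Na"]] * conc_in[["Na"]] + perm[["K"]] * conc_in[["K"]] +
    perm[["Cl"]] * conc_out[["Cl"]]
  if (den == 0 || num == 0) stop("GHK denominator/numerator is zero for these inputs")
  1000 * .R_GAS * temperature / .F_FARADAY * log(num / den)
}

#' Ionic composition of the recording solutions
#'
#' Total Na+, K+ and Cl- concentrations (mM) of the bath (ACSF: 127.99 NaCl,
#' 1.90 KCl, 2.40 CaCl2, 1.20 KH2PO4, 26.04 NaHCO3, ...) and the K-gluconate
#' pipette solution (140 K-gluconate, 1.32 CaCl2, ...), as used for the Nernst
#' and GHK calculations.
#'
#' @return list with named vectors \code{acsf} and \code{pipette}.
#' @export
tspn_solutions <- function() {
  list(acsf = c(Na = 127.99 + 26.04, K = 1.90 + 1.20, Cl = 127.99 + 1.90 + 2 * 2.40),
       pipette = c(Na = 0, K = 140, Cl = 2 * 1.32))
}
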