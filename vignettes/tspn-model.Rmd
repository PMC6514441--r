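---
title: "The tspn model: membrane mechanism, virtual experiments, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tspn model: membrane mechanism, virtual experiments, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspn)
```

## The model

`tspn` simulates a thoracic sympathetic postganglionic neuron (tSPN) as a single
electrotonically compact compartment. These cells have sparse dendritic arbors,
very high input resistance when recorded without impalement damage (hundreds of
megaohms to gigaohms), slow membrane time constants (tens to hundreds of ms) and
fire repetitively at low rates (under ~30 Hz). The membrane carries nine
currents,

$$C_m \frac{dV}{dt} = -\sum_i G_i\, m_i^{p_i} h_i^{q_i} (V - E_i) - I_{syn} + I_{inj},$$

with gating variables relaxing as $dx/dt = (x_\infty(V) - x)/\tau_x(V)$ and a
single intracellular calcium pool

$$\frac{d[\mathrm{Ca}^{2+}]}{dt} = \lambda\left(-\alpha I_{CaL} - k_{CaS}\,[\mathrm{Ca}^{2+}]\right),$$

with $\lambda = 0.01$ (free-to-bound ratio), $\alpha = 0.002\ \mu M\,ms^{-1}\,pA^{-1}$
and $k_{CaS} = 0.024\ ms^{-1}$, giving the pool an effective relaxation time of
about 4 s — the timescale of the slow phase of spike-rate adaptation.

The standard cell has $C_m = 100$ pF and maximal conductances (nS / reversal,
mV): Na 300/+60, CaL 1.2/+120, Kd 2000/−90, M 50/−90, KCa 50/−90, A 50/−90,
H 1/−32, leak 1/−55, and an impalement leak (0 by default) reversing at −15 mV.
The impalement reversal is the Goldman–Hodgkin–Katz potential of the recording
solutions under equal Na/K/Cl permeabilities (`ghk_reversal()` gives −13.8 mV,
i.e. ≈ −15 mV), representing the non-selective membrane breach made by a sharp
microelectrode. Injected current is depolarizing-positive; the printed form of
the current-balance equation is sign-ambiguous for the input term, and we fix
the convention every electrophysiologist uses.

### Kinetics are data

No gating parameterization is hard-coded. Each voltage-gated variable is a
Boltzmann steady state with a bell-shaped (possibly asymmetric) time constant;
the KCa activation is a Hill function of calcium. The parameter values live in
`inst/extdata/kinetics_standard.yaml` and can be swapped without touching the
integrator.

The shipped values are a *calibrated reconstruction*: they use the canonical
functional forms for each current family and were tuned so the standard cell
reproduces the documented tSPN phenotype — the impaled input resistance
(~100 MΩ at $g_{imp}$ = 7 nS), the ~7–8-fold rheobase increase under impalement,
repetitive firing from ~20 pA in high-resistance cells, the conversion of
repetitive to phasic firing with the shunt (non-firing → phasic near 200 pA),
M/KCa-separable spike-rate adaptation, the A-current notch, and the H-current
sag. Three structural choices deserve note:

* **M** uses a squared gate with a steep midpoint (−43.5 mV, k = 1.2, effective
  time constant 100–500 ms). This makes M effectively silent at the intact
  cell's interspike voltages (below −50 mV) while letting it dominate the
  shunted cell's depolarized plateau, which is what terminates firing after the
  onset burst. Phasic firing disappears (collapsing to a < 10 pA classification
  sliver at onset) when M is removed.
* **Na inactivation** is shallow and relatively fast (midpoint −41 mV, k = −7).
  Stability of the phasic plateau is carried by total conductance (shunt plus
  M chord), not by sodium block, so intact cells keep firing at high drive.
* **H** activates from about −76 mV and supplies much of the resting slope
  conductance of high-resistance cells. This sets the intact rheobase scale
  (~20 pA for the 0.5 nS-leak cell) while being irrelevant against a 7 nS
  shunt — the absolute conductance it adds is the same for both cells.

### Equilibrium potentials

`nernst()` and `ghk_reversal()` default to T = 295 K (room-temperature
recordings). `tspn_solutions()` carries the total Na/K/Cl content of the bath
and pipette solutions; the potassium equilibrium potential from the 140 mM
pipette against 3.1 mM bath is ≈ −97 mV.

## Virtual experiments

All protocols start from `steady_state_init()` and hold the cell at a target
potential with a bias current solved by bisection (`find_bias_current`,
tolerance 0.1 mV, bracket seeded by the analytic steady-state current sum and
scaled by the local slope conductance so near-gigaohm cells do not diverge).

* `measure_rheobase()`: binary search (default tolerance 0.5 pA, ceiling
  600 pA) for the minimal ≥ 1.5 s step eliciting ≥ 1 spike. Cells that cannot
  spike raise a `tspn_not_excitable` condition.
* `strength_duration()`: the same search per duration; monotone non-increasing
  with the rheobase as the long-duration asymptote.
* `fi_curve()`: maximal rate = inverse first interspike interval; sustained
  rate = mean rate of the last three intervals provided the spikes closing them
  fall in the last half of the step (this qualification matches the worked
  definition of the sustained rate); slopes by least squares.
* `classify_firing()`: N = no spikes in the step; P = spikes confined to the
  first half; R = any spike in the final half. The corner case of exactly one
  spike falling in the final half is classified R. Near a cell's firing onset
  this rule can produce a thin (few-pA) P sliver where the first spike exists
  but sustained firing has not yet locked in; boundary consumers should treat
  slivers narrower than ~10 pA as discretization of the onset, not as a phasic
  regime.
* `phase_boundaries()`: per impalement conductance, binary searches for the
  N-boundary and, if the class above onset is phasic, a grid-then-bisect search
  for the repetitive window (the class sequence need not be monotone: at very
  high drive intact cells can enter depolarization block). The default ceiling
  is 600 pA; the minimal repetitive current of the shunted cell lies above it,
  so that search is run with a 1500 pA ceiling.
* `knockout()`: returns a copy with the named maximal conductances set to zero;
  knockouts commute.

## Feature extraction

`fit_passive()` fits $\Delta V e^{-t/\tau_m} + (V_{hold} - \Delta V)$ by
Levenberg–Marquardt, then $R_{in} = \Delta V/|I|$ and $C_m = \tau_m/R_{in}$.
`detect_threshold()` operationalizes "where $dV/dt$ begins to increase" as the
last sample before the maximal-upstroke point at which the smoothed derivative
crosses a criterion from below. The default criterion is 1 mV/ms: the model's
action potentials accelerate gently near their foot, and a 5 mV/ms criterion
lands several millivolts above the inflection; doubling the 1 mV/ms criterion
moves the threshold by less than 2 mV. AP metrics (peak, amplitude, half-width,
rise slope), fAHP metrics (only for single-spike minimal-suprathreshold
traces), sAHP metrics (after step offset), firing rates/SRA ratio, sag, rebound
and notch detectors follow the definitions in the function documentation. The
notch is measured as the maximal deviation of the pre-spike trajectory below a
fitted single exponential (criterion 1 mV): a hyperpolarized hold
de-inactivates the A current, which stalls the charging trajectory and delays
the first spike severalfold. `ljp_correct()` subtracts the fixed 10 mV liquid
junction offset from absolute voltages only.

One known bias: because H contributes strongly below rest, the input resistance
measured with a hyperpolarizing probe exceeds the effective resistance seen by
a depolarizing approach to threshold. Calculated rheobase
$(V_{th}-V_{hold})/R_{in}$ therefore correlates strongly with measured rheobase
across a synthetic population (r > 0.8) but sits above the identity line.

## The synthetic population

`sample_population()` draws maximal conductances from log-normal distributions
(positive and right-skewed) and capacitance from a truncated normal
(89 ± 27 pF on [51, 157]), rejecting cells that are unstable or spontaneously
active at rest. The defaults emulate the recorded heterogeneity: input
resistances span roughly 250–2300 MΩ with time constants from tens to hundreds
of ms. The generator emulates *passive and conductance heterogeneity only* — it
does not model correlated channel expression, dendritic filtering, electrode
series-resistance artifacts or synaptic background, so passing population tests
demonstrate the pipeline's internal consistency, not fidelity to any recorded
dataset. `correlate()` computes Pearson r with two-tailed t p-values on
pairwise-complete observations and flags significance at the Šidák-corrected
level ($\alpha' = 1-(1-\alpha)^{1/m}$; 0.0017 for $\alpha = 0.05$, m = 30).

## Synaptic drive

Unitary conductances are double exponentials (rise 1 ms, decay 15 ms)
normalized in closed form to unit peak, summed into a dense waveform from
Poisson event times with log-normal amplitudes (median ~0.6 nS, occasional
multi-nS events; the published description of the recorded amplitudes is
qualitative, so the distribution is a package choice exposed in the arguments).
Driving the standard cell at −60 mV with this template recruits spikes through
temporal summation; adding the 7 nS impalement shunt abolishes summation-driven
recruitment, leaving at most the largest single event effective.

## Numerical choices

Integration is exponential-Euler at dt = 0.1 ms: gates take their exact
exponential update; the voltage relaxes toward the conductance-weighted
reversal at the instantaneous total-conductance rate; calcium is advanced the
same way from the instantaneous CaL current. Non-finite state or |V| > 200 mV
aborts with an error naming the step. Against a dt = 0.01 ms reference, spike
counts are identical and spike-time drift accumulates roughly linearly along a
train (first spikes agree to ~0.1 ms; at moderate rates the full 1.5 s train
stays within 2 ms, at 200 pA the latest spikes drift to ~2.5 ms). The passive
limit matches the analytic RC response to better than 0.5%.

Problem sizes in the shipped tests were chosen to keep the default suite fast:
1.5–3 s steps, populations of 8–30 cells, 200–500 replicate draws for
noise/calibration studies. The acceptance script reruns every search from
scratch (about seventy 1.5–3 s integrations in total).

## Known limitations

* **Post-inhibitory rebound.** The recorded phenomenology attributes rebound
  firing after ~10 mV hyperpolarization from a −50 mV hold to the M current
  (surviving H removal, lost with M removal). With the printed conductances and
  any monotone Boltzmann M activation, the M density required at −50 mV to
  drive the rebound exceeds the density at −48 mV compatible with 20 pA
  repetitive firing in the high-resistance cell — the two constraints are
  mutually exclusive for this kinetics family (sodium de-inactivation
  contributes under 1 mV of assist). The shipped kinetics therefore do not
  produce rebound at a −50 mV hold, and the corresponding acceptance test
  documents the discrepancy rather than masking it. A two-component M model (a
  second, more hyperpolarized slow gate) would likely reconcile the two.
* The spike-rate-adaptation decomposition is demonstrated at 80 pA: the
  adaptation-figure cell's reconstructed rheobase is ~53 pA, so the 50 pA used
  for the recorded cell is subthreshold here.
* Action potentials are narrower (half-width ~2 ms) than the recorded mean
  (4.6 ms); none of the reproduced quantities depend on spike width.
* No ultra-slow AHP mechanism (Na/K-ATPase) is modelled; `usahp_flag()` only
  detects the signature.

## A worked example

```{r example, eval = FALSE}
cell <- tspn_neuron()                         # standard cell
summary(cell)                                 # R_in and nominal tau at -70 mV
rheo <- measure_rheobase(cell)                # ~30 pA
impaled <- tspn_neuron(g = c(imp = 7))
measure_rheobase(impaled) / rheo              # ~7-fold increase

f5 <- tspn_neuron("fig5")
phase_boundaries(f5, c(0, 7))                 # N/P/R boundaries

tr <- run_step(cell, 100, hold_v = -70, step_ms = 3000)
plot(tr)
firing_rates(detect_spikes(tr), tr$meta$window)$sra_ratio
```
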