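# tspn

Conductance-based modelling of thoracic sympathetic postganglionic neurons
(tSPNs) — the paravertebral chain cells that form the final output of the
sympathetic nervous system. Whole-cell recordings show these neurons with
input resistances an order of magnitude above classical sharp-microelectrode
values, rheobases of only tens of picoamps, and universal repetitive firing;
the old picture of leaky, phasically firing relays turns out to be an artifact
of the impalement injury conductance. `tspn` packages a single-compartment
Hodgkin–Huxley-style model of these cells together with the virtual
experiments that demonstrate this, and a patch-clamp feature-extraction
pipeline for the resulting (or any compatible) voltage traces.

The membrane obeys

    C_m dV/dt = -Σ_i G_i m^p h^q (V - E_i) - I_syn + I_inj

with nine currents (fast Na, delayed-rectifier Kd, slow non-inactivating M,
calcium-dependent KCa, fast transient A, hyperpolarization-activated H,
persistent CaL, ohmic leak, and an ohmic impalement leak reversing at −15 mV),
first-order gating kinetics, a single calcium pool driving KCa, and
double-exponential synaptic conductances. Integration is exponential-Euler at
0.1 ms. Gating parameterizations are *data*, shipped as a versioned YAML
configuration (`inst/extdata/kinetics_standard.yaml`) and calibrated so the
standard cell reproduces the documented tSPN phenotype; see the methods
vignette (`vignettes/tspn-model.Rmd`) for the model, the calibration logic and
its limitations.

What it does:

* **Model construction** — `tspn_neuron()` with named presets for the
  per-experiment parameter variants, `knockout()` for conductance removal,
  `coef()`/`print()`/`summary()`/`simulate()`/`plot()` methods.
* **Virtual experiments** — bias-current holding (`find_bias_current`),
  rheobase binary search (`measure_rheobase`), strength–duration curves,
  f–I curves with maximal/sustained rates, firing-type classification
  (non-firing / phasic / repetitive) and phase diagrams over the
  (impalement conductance, injected current) plane (`phase_boundaries`),
  Poisson synaptic drive (`synaptic_event_train`,
  `generate_synaptic_conductance`).
* **Feature extraction** — passive fits (Levenberg–Marquardt), spike and
  threshold detection, AP/fAHP/sAHP metrics, instantaneous firing rates and
  spike-rate-adaptation ratio, sag/rebound/notch detection, liquid-junction
  correction, and a per-cell pipeline (`extract_features`).
* **Synthetic populations & statistics** — `sample_population()` emulating the
  recorded cell-to-cell heterogeneity; `correlate()` for Pearson r with
  Šidák-corrected significance.
* **I/O and CLI** — plain-text trace files (`write_trace`/`read_trace`) and a
  thin command-line interface (`tspn_cli()`, shipped as `inst/exec/tspn`) with
  subcommands `simulate | rheobase | sd-curve | fi-curve | phase-diagram |
  features | population | knockout`.

## A worked example

```r
library(tspn)

cell <- tspn_neuron()          # standard model cell
summary(cell)
#> tSPN model neuron (preset 'standard', kinetics 'standard')
#>   C_m: 100 pF
#>   conductances (nS): Na=300, CaL=1.2, Kd=2000, M=50, KCa=50, A=50, H=1, leak=1, imp=0
#>   reversals (mV):    Na=60, CaL=120, Kd=-90, M=-90, KCa=-90, A=-90, H=-32, leak=-55, imp=-15
#>   at -70 mV hold: R_in = 399 MOhm, nominal tau_m = 39.9 ms, rest [Ca] = 0.0048 uM

measure_rheobase(cell)         # minimal 1.5 s step that elicits a spike
#> [1] 30.32227                 # pA

impaled <- tspn_neuron(g = c(imp = 7))   # simulated microelectrode impalement
model_input_resistance(impaled)
#> [1] 106.9243                 # MOhm -- the classical sharp-electrode value
measure_rheobase(impaled) / measure_rheobase(cell)
#> [1] 7.09                     # impalement raises rheobase ~7-fold

fi <- fi_curve(tspn_neuron("fig4"), c(70, 90, 110, 130))
as.data.frame(fi)
#>   current_pa max_rate sustained_rate
#> 1         70 10.04016       4.522153
#> 2         90 17.12329       6.813493
#> 3        110 22.88330       8.601328
#> 4        130 27.93296       9.945135
```

The maximal rate is the inverse first interspike interval (initial burst), the
sustained rate the mean of the last three intervals — the gap between them is
the spike-rate adaptation carried by the M and KCa currents. The phase diagram
of firing type under impalement is one call:

```r
phase_boundaries(tspn_neuron("fig5"), c(0, 7))
#>   g_imp  n_to_p n_to_r  p_to_r
#> 1     0      NA     NA    20.1    # repetitive firing above ~20 pA
#> 2     7   201.4     NA      NA    # shunted: phasic above ~200 pA
```

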