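# Standard gating kinetics for the tSPN model, version 1.
#
# Every voltage-gated variable x uses a Boltzmann steady state and a bell-shaped
# time constant:
#   x_inf(V) = 1 / (1 + exp((vhalf - V)/k))        # k < 0 -> falling (inactivation / H)
#   tau_x(V) = tau_min + tau_amp / (exp((V - tau_vhalf)/tau_k1) + exp(-(V - tau_vhalf)/tau_k2))
# Units: mV for voltages, ms for time constants.
#
# The calcium-gated KCa activation uses a Hill function of the intracellular
# calcium concentration (uM) with a fixed time constant:
#   z_inf(Ca) = Ca^hill / (Ca^hill + kd^hill)
#
# The functional forms follow the classical single-compartment treatments of each
# current family (fast Na / delayed rectifier / M-type / A-type / H / L-type Ca /
# SK-like KCa). The numerical values are a calibrated set: they were chosen so the
# standard model cell reproduces the recorded tSPN phenotype (slow ~4-5 ms action
# potentials, repetitive firing up to ~30 Hz, M- and KCa-mediated adaptation,
# A-mediated notch, H-mediated sag at deep hyperpolarization) and its documented
# behaviour under impalement-shunt simulations. Alternative parameterizations can
# be swapped in without touching the integrator: kinetics are data, not code.
version: 1
name: standard
channels:
  Na:
    p: 3
    q: 1
    activation:   {vhalf: -34.1, k: 5.0,  tau_min: 0.1,  tau_amp: 1.2,   tau_vhalf: -40.0, tau_k1: 15.0, tau_k2: 15.0}
    inactivation: {vhalf: -41.0, k: -7.0, tau_min: 2.0,  tau_amp: 30.0,  tau_vhalf: -55.0, tau_k1: 15.0, tau_k2: 15.0}
  Kd:
    p: 4
    activation:   {vhalf: -25.0, k: 9.0,  tau_min: 2.5,  tau_amp: 20.0,  tau_vhalf: -30.0, tau_k1: 20.0, tau_k2: 8.0}
  M:
    p: 2
    activation:   {vhalf: -43.5, k: 1.2,  tau_min: 100.0, tau_amp: 400.0, tau_vhalf: -35.0, tau_k1: 100.0, tau_k2: 20.0}
  KCa:
    p: 1
    calcium:      {kd: 3.0, hill: 2.0, tau: 50.0}
  A:
    p: 3
    q: 1
    activation:   {vhalf: -44.0, k: 7.0,  tau_min: 1.0,  tau_amp: 5.0,   tau_vhalf: -50.0, tau_k1: 20.0, tau_k2: 20.0}
    inactivation: {vhalf: -80.0, k: -5.0, tau_min: 50.0, tau_amp: 200.0, tau_vhalf: -85.0, tau_k1: 20.0, tau_k2: 20.0}
  H:
    p: 1
    activation:   {vhalf: -76.5, k: -8.0, tau_min: 100.0, tau_amp: 1000.0, tau_vhalf: -90.0, tau_k1: 15.0, tau_k2: 15.0}
  CaL:
    p: 1
    activation:   {vhalf: -12.0, k: 7.0,  tau_min: 2.0,  tau_amp: 10.0,  tau_vhalf: -30.0, tau_k1: 15.0, tau_k2: 15.0}
  leak: {}
  imp:  {}
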