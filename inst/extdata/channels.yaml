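# Spatial channel-density table for the dSPN model: one rule per channel
# per region.  Rules follow the distribution conventions of the antecedent
# striatal projection-neuron models,
#   sigmoidal:    (a4 + a5/(1 + exp((x - a6)/a7))) * gmax
#   exponential:  (a4 + a5*exp((x - a6)/a7))       * gmax
#   uniform:      gmax
# with x the path distance (um) from the centre of the soma, evaluated from
# the soma surface (x = 6.010) and capped at the furthest dendritic point.
# gmax is S/cm2 for ohmic channels and cm/s (GHK permeability) for calcium
# channels.  Densities were calibrated against the model's passive surface
# (resting potential -84 mV, rectified-range input resistance ~85 MOhm,
# membrane time constant ~10.5 ms) and a clustered-input plateau threshold
# of 15 glutamatergic synapses.

temp_K: 307.15
ions:
  na: 50.0
  k: -90.0
leak:
  e_pas: -70.0
calcium:
  rest_mM: 5.0e-5
  tau_ms: 20.0
  depth_um: 0.1
  cao_mM: 2.0
mg_block:
  conc_mM: 1.0
  k_mM: 3.57
  gamma_per_mV: 0.062

channels:
  naf:
    soma: {kind: uniform, gmax: 0.25}
    dend: {kind: sigmoidal, a4: 0.05, a5: 0.95, a6: 50.0, a7: 15.0, gmax: 0.02}
  nap:
    soma: {kind: uniform, gmax: 4.0e-5}
    dend: {kind: uniform, gmax: 1.0e-5}
  kaf:
    soma: {kind: uniform, gmax: 0.10}
    dend: {kind: sigmoidal, a4: 0.05, a5: 0.95, a6: 65.0, a7: 20.0, gmax: 0.62}
  kas:
    soma: {kind: uniform, gmax: 0.02}
    dend: {kind: exponential, a4: 0.1, a5: 0.9, a6: 6.01, a7: -40.0, gmax: 0.008}
  kir:
    soma: {kind: uniform, gmax: 1.0e-4}
    dend: {kind: uniform, gmax: 1.0e-4}
  kdr:
    soma: {kind: uniform, gmax: 0.002}
    dend: {kind: uniform, gmax: 5.0e-4}
  sk:
    soma: {kind: uniform, gmax: 1.0e-5}
    dend: {kind: uniform, gmax: 1.0e-5}
  bk:
    soma: {kind: uniform, gmax: 1.0e-5}
    dend: {kind: uniform, gmax: 5.0e-6}
  cav12:
    soma: {kind: uniform, gmax: 1.0e-5}
    dend: {kind: sigmoidal, a4: 0.0, a5: 1.0, a6: 60.0, a7: 10.0, gmax: 1.0e-5}
  cav13:
    soma: {kind: uniform, gmax: 1.0e-6}
    dend: {kind: sigmoidal, a4: 0.1, a5: 0.9, a6: 85.0, a7: -25.0, gmax: 2.0e-5}
  cav22:
    soma: {kind: uniform, gmax: 1.0e-5}
    dend: {kind: uniform, gmax: 1.0e-6}
  cav23:
    soma: {kind: uniform, gmax: 1.0e-6}
    dend: {kind: uniform, gmax: 2.0e-6}
  cav32:
    soma: {kind: uniform, gmax: 1.0e-6}
    dend: {kind: sigmoidal, a4: 0.0, a5: 1.0, a6: 85.0, a7: -30.0, gmax: 2.0e-5}
  cav33:
    soma: {kind: uniform, gmax: 1.0e-6}
    dend: {kind: sigmoidal, a4: 0.0, a5: 1.0, a6: 85.0, a7: -30.0, gmax: 3.0e-5}
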