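# Hodgkin-Huxley-style gating schemes for the 14 somatodendritic channels.
#
# Voltage gates: steady state 1/(1 + exp((vhalf - V)/slope)) (slope < 0
# gives inactivation) and time constant tau_base + tau_amp /
# (exp((V - tau_vhalf)/tau_s1) + exp(-(V - tau_vhalf)/tau_s2)) ms
# (tau_amp = 0 means a constant tau_base).  Calcium gates: Hill activation
# of SK; BK opens with joint depolarization and calcium.  Values are an
# internally calibrated parameterization in the conventions of published
# striatal projection-neuron models; they live here, not in code, so a
# substitution needs no code change.
#
# mV, ms, mM throughout.

naf:
  ion: na
  gates:
    - {name: m, power: 3, kind: voltage, vhalf: -23.0, slope: 8.0,
       tau_base: 0.05, tau_amp: 0.6, tau_vhalf: -35.0, tau_s1: 12.0, tau_s2: 12.0}
    - {name: h, power: 1, kind: voltage, vhalf: -60.0, slope: -7.0,
       tau_base: 0.25, tau_amp: 6.0, tau_vhalf: -58.0, tau_s1: 14.0, tau_s2: 14.0}
nap:
  ion: na
  gates:
    - {name: m, power: 1, kind: voltage, vhalf: -47.8, slope: 3.1,
       tau_base: 1.0, tau_amp: 0.0}
kaf:
  ion: k
  gates:
    - {name: m, power: 2, kind: voltage, vhalf: -25.0, slope: 13.0,
       tau_base: 0.5, tau_amp: 1.5, tau_vhalf: -30.0, tau_s1: 20.0, tau_s2: 20.0}
    - {name: h, power: 1, kind: voltage, vhalf: -72.0, slope: -9.0,
       tau_base: 10.0, tau_amp: 25.0, tau_vhalf: -50.0, tau_s1: 20.0, tau_s2: 20.0}
kas:
  ion: k
  gates:
    - {name: m, power: 2, kind: voltage, vhalf: -27.0, slope: 12.0,
       tau_base: 3.0, tau_amp: 15.0, tau_vhalf: -40.0, tau_s1: 25.0, tau_s2: 25.0}
    - {name: h, power: 1, kind: voltage, vhalf: -60.0, slope: -12.0,
       tau_base: 150.0, tau_amp: 0.0}
kir:
  ion: k
  gates:
    - {name: m, power: 1, kind: voltage, vhalf: -102.0, slope: -12.5,
       tau_base: 1.0, tau_amp: 0.0}
kdr:
  ion: k
  gates:
    - {name: m, power: 2, kind: voltage, vhalf: -13.0, slope: 10.0,
       tau_base: 1.0, tau_amp: 6.0, tau_vhalf: -30.0, tau_s1: 20.0, tau_s2: 20.0}
sk:
  ion: k
  gates:
    - {name: z, power: 1, kind: ca_hill, hill: 4, ec50: 0.00035, tau: 4.0}
bk:
  ion: k
  gates:
    - {name: o, power: 1, kind: bk, vhalf: -10.0, slope: 12.0,
       ca_ref: 0.004, tau: 1.0}
cav12:
  ion: ca
  gates:
    - {name: m, power: 2, kind: voltage, vhalf: -8.9, slope: 6.7,
       tau_base: 0.2, tau_amp: 2.0, tau_vhalf: -15.0, tau_s1: 15.0, tau_s2: 15.0}
    - {name: h, power: 1, kind: voltage, vhalf: -13.4, slope: -11.9,
       tau_base: 44.3, tau_amp: 0.0}
cav13:
  ion: ca
  gates:
    - {name: m, power: 1, kind: voltage, vhalf: -33.0, slope: 6.7,
       tau_base: 0.5, tau_amp: 2.0, tau_vhalf: -30.0, tau_s1: 15.0, tau_s2: 15.0}
    - {name: h, power: 1, kind: voltage, vhalf: -13.4, slope: -11.9,
       tau_base: 44.3, tau_amp: 0.0}
cav22:
  ion: ca
  gates:
    - {name: m, power: 2, kind: voltage, vhalf: -8.7, slope: 7.4,
       tau_base: 0.4, tau_amp: 1.8, tau_vhalf: -15.0, tau_s1: 15.0, tau_s2: 15.0}
    - {name: h, power: 1, kind: voltage, vhalf: -74.8, slope: -6.5,
       tau_base: 70.0, tau_amp: 0.0}
cav23:
  ion: ca
  gates:
    - {name: m, power: 3, kind: voltage, vhalf: -10.3, slope: 6.6,
       tau_base: 1.5, tau_amp: 2.0, tau_vhalf: -20.0, tau_s1: 15.0, tau_s2: 15.0}
    - {name: h, power: 1, kind: voltage, vhalf: -33.3, slope: -17.0,
       tau_base: 78.0, tau_amp: 0.0}
cav32:
  ion: ca
  gates:
    - {name: m, power: 3, kind: voltage, vhalf: -50.0, slope: 6.0,
       tau_base: 2.0, tau_amp: 10.0, tau_vhalf: -55.0, tau_s1: 18.0, tau_s2: 18.0}
    - {name: h, power: 1, kind: voltage, vhalf: -72.0, slope: -7.0,
       tau_base: 50.0, tau_amp: 100.0, tau_vhalf: -60.0, tau_s1: 15.0, tau_s2: 15.0}
cav33:
  ion: ca
  gates:
    - {name: m, power: 3, kind: voltage, vhalf: -44.0, slope: 6.0,
       tau_base: 4.0, tau_amp: 25.0, tau_vhalf: -50.0, tau_s1: 18.0, tau_s2: 18.0}
    - {name: h, power: 1, kind: voltage, vhalf: -70.0, slope: -7.0,
       tau_base: 100.0, tau_amp: 200.0, tau_vhalf: -60.0, tau_s1: 15.0, tau_s2: 15.0}
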