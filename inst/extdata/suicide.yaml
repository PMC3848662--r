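# Suicide-substrate (mechanism-based inhibition) reaction.
# Partition ratio r = k3/k4 = 5, mu = e0/s0 = 1, (1+r)*mu = 6 > 1:
# the substrate is exhausted before all enzyme is inactivated.
domain:
  a: 2.0
  b: 1.0
  h: 0.1
model:
  preset: suicide
  constants:
    k1: 2.0              # muM^-1 s^-1
    km1: 4.0
    k2: 12.0
    k3: 10.0
    k4: 2.0
    e0: 0.5
    s0: 0.5
species:
  - {name: "E",  d: 1.0e-3, z: 1, C0: 0.5}
  - {name: "S",  d: 2.0e-3, z: 0, C0: 0.5}
  - {name: "X",  d: 5.0e-3, z: 1, C0: 0.0}
  - {name: "Y",  d: 1.0e-3, z: 1, C0: 0.0}
  - {name: "Ei", d: 2.0e-3, z: 1, C0: 0.0}
  - {name: "P",  d: 4.0e-6, z: 0, C0: 0.0}
epsilon: 1.0e6
fixed_charge: 0.1
phi0: {value: -80, unit: mV}
solver:
  dt: 1.0e-2
  T: 4.0
  eps: 1.0e-4
  max_picard: 50
probes:
  - [0.0, 0.0]
output:
  directory: pnpfem_suicide
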