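# Cooperative two-site binding, positive cooperativity (K1 = 1000,
# K2 = 0.001; slow first binding, fast second -> sigmoidal product curve).
# Negative cooperativity: K1 = 0.5, K2 = 100.
domain:
  a: 2.0
  b: 1.0
  h: 0.1
model:
  preset: cooperative
  constants:
    K1: 1000.0
    K2: 1.0e-3
    km1: 1.0
    k2: 1.0
    km3: 1.0
    k4: 1.0
    e0: 0.5
    s0: 0.5
species:
  - {name: "E", d: 1.0e-3, z: 1, C0: 0.5}
  - {name: "S", d: 2.0e-3, z: 0, C0: 0.5}
  - {name: "X", d: 5.0e-3, z: 1, C0: 0.0}
  - {name: "Y", d: 1.0e-3, z: 1, C0: 0.0}
  - {name: "P", d: 2.0e-3, z: 0, C0: 0.0}
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
  directory: pnpfem_cooperative
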