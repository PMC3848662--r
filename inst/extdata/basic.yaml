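# Basic (Michaelis-Menten) enzyme reaction in an elliptical cell.
# Concentrations in muM unless a unit is given; kM is entered in molar
# units and converted on load (9e-5 M = 90 muM).
domain:
  a: 2.0
  b: 1.0
  h: 0.1
model:
  preset: basic
  constants:
    k2: 1.4e4            # 1/s
    kM: {value: 9.0e-5, unit: M}
    C10: 1.0             # total enzyme, muM
species:
  - {name: "E", d: 1.0e-3, z: 1, C0: 1.0}
  - {name: "S", d: 2.0e-3, z: 0, C0: 800.0}
  - {name: "P", d: 5.0e-3, z: 1, C0: 0.0}
epsilon: 1.0e6           # weak charge coupling: muM-scale net charge -> sub-mV potentials
fixed_charge: 0.1
phi0: {value: -80, unit: mV}
solver:
  dt: 1.0e-3
  T: 0.2
  eps: 1.0e-4
  max_picard: 50
  V_T: 25.693
probes:
  - [0.0, 0.0]           # centre of the cell
output:
  directory: pnpfem_basic
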