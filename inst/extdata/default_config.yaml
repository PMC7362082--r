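# fibrinet configuration — all values shown are the package defaults.
# Any key may be omitted; omitted keys take these defaults.
# Units: pN, nm at the molecule/fiber scale; mm / um / fibers per um^3 at
# the clot scale (converted internally).
parameters:
  k1: 1.5        # linear monomer stiffness, pN/nm
  k2: 0.0003     # cubic monomer stiffness, pN/nm^3
  d2: 46.0       # cubic onset = fibrinogen length, nm
  k3: 130.0      # knob-hole (D-E) saturation force, pN
  d3: 10.0       # knob-hole extension scale, nm
  k4: 13.0       # gamma-gamma (D-D) saturation force, pN
  d4: 20.0       # gamma-gamma extension scale, nm
  k5: 0.1        # binding linear stiffness, pN/nm (0 switches binding off)
  k6: 0.0002     # binding cubic stiffness, pN/nm^3 (convention: k5/500)
  d5: 11.5       # binding cubic onset, nm (element rest length / 4)
fiber:
  fiber_length: 12000.0        # nm
  fiber_diameter: 330.0        # nm
  protein_fraction: 0.30
  monomer_radius: 2.25         # nm
  element_rest_length: 46.0    # nm
clot:
  clot_diameter_mm: 2.0
  fiber_density_per_um3: 0.5
  fiber_length_um: 12.0
simulation:
  force_max: 200.0    # pN per monomer
  n_steps: 500
  solver_tolerance: 1.0e-8    # residual 2-norm, pN
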