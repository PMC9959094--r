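# Example configuration for `mesodiff.R simulate` / run_simulate().
# Units: nm, ns, kBT; times in tau = 1/Dwat.
profile:
  dU: 3        # tail-plateau free energy (kBT); > 0 = hydrophilic
  dUb: 5       # head barrier (kBT); < 0 digs an interfacial well
  a: 6.65      # lattice parameter (nm)
  l: 2.365     # lipid length (nm)
  h: 1.0       # head size (nm)
diffusion:
  Dwat: 0.7        # bulk-water diffusivity (nm^2/ns)
  dlip_ratio: 0.09 # Dlip = 0.09 Dwat
  w: 0.96          # reduced-mobility layer thickness (nm)
dynamics:
  n_particles: 400
  t_total: 3000    # tau
  dt: 3.0e-4       # tau
  seed: 1
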