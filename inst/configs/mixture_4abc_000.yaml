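# 80 vol% surfactant lamellar equilibration + dissolution
# mixture: 100% 3A2BC / 0% 4ABC (of the surfactant fraction)
composition:
  3A2BC: 0.800
  water: 0.200
box: [20, 20, 20]
schedule:
  equilibrate_steps: 20000
  n_layers: 4
  relax_steps: 10000
  dissolve_steps: 100000
  stride: 2000
  end_conc: 0.2
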