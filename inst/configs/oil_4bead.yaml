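# 70 vol% 3A2BC + 10 vol% oil lamellar equilibration + dissolution
# oil chain length: 4 bead(s)
composition:
  3A2BC: 0.700
  oil4: 0.100
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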