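# reduced-scale demonstration (minutes on one CPU)
composition:
  3A2BC: 0.8
  water: 0.2
box: [10, 10, 10]
schedule:
  equilibrate_steps: 2000
  n_layers: 2
  relax_steps: 1000
  dissolve_steps: 8000
  stride: 500
  end_conc: 0.2
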