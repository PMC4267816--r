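# Direction-selectivity training: repeated upward sweeps at 320 cells/s
# applied to an initially symmetric plastic sideband circuit.
circuit:
  type: sideband
  mean_inhib: 0.183
  plastic: true
training:
  n_trials: 200
  rate: 320
  record_dsi_every: 25
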