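# Fast-pass rate selectivity of the sideband-inhibition circuit:
# 10 variants along the mean input-to-inhibitory weight.
circuit:
  type: sideband
scan:
  mode: spikes
  family:
    knob: mean_inhib
    values: [0.18, 0.22, 0.26, 0.30, 0.34, 0.38, 0.42, 0.46, 0.50, 0.55]
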