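# Band-pass coincidence detection: variants along the slow synaptic delay.
circuit:
  type: facilitation
scan:
  mode: spikes
  family:
    knob: delay_slow
    values: [3, 5, 7, 9, 11, 13, 15, 17, 19]
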