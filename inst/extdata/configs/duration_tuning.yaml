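# Duration tuning (anti-coincidence regime): variants along the weak
# integrative weight; scanned over tone durations of 1..12 input spikes.
circuit:
  type: duration
  regime: anti
scan:
  mode: spikes
  counts: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
  family:
    knob: w_weak
    values: [0.10, 0.11, 0.12, 0.14, 0.16]
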