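schema_version: '1'
bandpass_low_hz: 2.0
bandpass_high_hz: 20.0
epoch_length_ms: 2000.0
q_range:
- 2
- 8
polarity_invariant: yes
smoothing_min_ms: 0.0
alpha_family: 0.05
n_comparisons: 4
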