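fs: 250.0
channel_names:
- ch1
- ch2
- ch3
- ch4
- ch5
- ch6
reference: average
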