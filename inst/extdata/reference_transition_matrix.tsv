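from	low	medium	high
low	0.8895	0.1105	0.0000
medium	0.1343	0.7214	0.1443
high	0.0338	0.1498	0.8164
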