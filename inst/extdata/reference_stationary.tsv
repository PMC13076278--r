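state	pi
low	0.4491
medium	0.3084
high	0.2424
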