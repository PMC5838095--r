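year,proportion
2005,0.35
2016,0.74
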