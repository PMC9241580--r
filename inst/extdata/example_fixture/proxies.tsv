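original	proxy	r2
rs12188917	rs3091307	0.9
rs6419573	rs1035127	0.85
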