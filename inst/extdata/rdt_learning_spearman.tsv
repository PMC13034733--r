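variable	pick_count	trials_to_learn	dft	wme
pick_count	1	0.77	0.59	0.69
trials_to_learn	0.77	1	0.80	0.56
dft	0.59	0.80	1	0.33
wme	0.69	0.56	0.33	1
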