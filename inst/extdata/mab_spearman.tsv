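variable	exploratory_diversity	neophobia	persistence	inhibitory
exploratory_diversity	1	-0.36	0.40	-0.35
neophobia	-0.36	1	-0.47	0.77
persistence	0.40	-0.47	1	-0.77
inhibitory	-0.35	0.77	-0.77	1
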