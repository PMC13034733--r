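locus	private_alleles	n_alleles	ho	he	pic
gpz20	9	9	0.214	0.897	0.85
gpz6	6	8	0.308	0.883	0.831
gpz47	5	7	0.944	0.814	0.764
GPL8	4	4	0.125	0.742	0.645
GPL60	6	6	0.063	0.736	0.668
gpy5	4	4	0	0.762	0.678
GPL29	3	3	0	0.594	0.477
gpy20	2	2	0	0.173	0.152
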