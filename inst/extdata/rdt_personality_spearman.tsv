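variable	llvr	llsd	accuracy	tlv
llvr	1	-0.09	-0.20	-0.44
llsd	-0.09	1	-0.81	0.34
accuracy	-0.20	-0.81	1	-0.17
tlv	-0.44	0.34	-0.17	1
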