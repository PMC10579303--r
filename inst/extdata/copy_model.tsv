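guild	marker	copies
prokaryote	rpoB	1
AOA	amoA	1
AOB	amoA	2.5
comammox	amoA	1.5
Nitrospira	nxrB	4
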