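marker	CultureA_synthetic	CultureB_synthetic	CultureC_synthetic
rpoB	0	0	0
amoA	3.2	2.8	3.5
nirK	2.1	X	1.4
ureC	-2	X	0.5
ut	-3	X	nd
accB	0.8	1.1	0.9
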