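trait	OP	SOR	IP	singleton
abiotic_stress	18	32	0	0
biotic_stress	31	15	1	3
architecture	3	6	0	0
heading	3	6	0	0
quality	6	9	0	1
yield	19	27	0	0
other	3	4	0	0
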