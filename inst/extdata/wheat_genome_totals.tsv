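genome	total_genes
AK58	119448
CS	106925
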