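genome	type	families	genes
AK58	IP	3693	8957
AK58	dyad	2154	5649
AK58	triplet	6915	29962
AK58	OP	4314	13131
AK58	SOR	13780	41340
CS	IP	2772	6532
CS	dyad	1898	4748
CS	triplet	6690	29280
CS	OP	4299	13068
CS	SOR	13393	40179
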