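type	genome	region	pi
IP	AK58	upstream2kb	0.2852
IP	AK58	utr5	0.1002
IP	AK58	cds	0.0699
IP	AK58	utr3	0.1105
IP	CS	upstream2kb	0.3477
IP	CS	utr5	0.1552
IP	CS	cds	0.0791
IP	CS	utr3	0.1744
OP	AK58	upstream2kb	0.4675
OP	AK58	utr5	0.3774
OP	AK58	cds	0.2451
OP	AK58	utr3	0.3965
OP	CS	upstream2kb	0.4720
OP	CS	utr5	0.3734
OP	CS	cds	0.2467
OP	CS	utr3	0.3966
SOR	AK58	upstream2kb	0.2974
SOR	AK58	utr5	0.0802
SOR	AK58	cds	0.0343
SOR	AK58	utr3	0.0851
SOR	CS	upstream2kb	0.3242
SOR	CS	utr5	0.0822
SOR	CS	cds	0.0344
SOR	CS	utr3	0.0913
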