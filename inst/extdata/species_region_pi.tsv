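species	region	type	pi
T_urartu	upstream2kb	IP	0.4354
T_urartu	cds	IP	0.1303
T_urartu	gene_body	IP	0.1722
Ae_tauschii	upstream2kb	IP	0.5613
Ae_tauschii	cds	IP	0.2006
Ae_tauschii	gene_body	IP	0.2106
T_dicoccoides	upstream2kb	IP	0.4799
T_dicoccoides	upstream2kb	OP	0.5559
T_dicoccoides	upstream2kb	SOR	0.4511
T_dicoccoides	cds	IP	0.1277
T_dicoccoides	cds	OP	0.1565
T_dicoccoides	cds	SOR	0.0428
T_dicoccoides	gene_body	IP	0.1587
T_dicoccoides	gene_body	OP	0.2535
T_dicoccoides	gene_body	SOR	0.0871
Fielder	upstream2kb	IP	0.2758
Fielder	upstream2kb	OP	0.5440
Fielder	upstream2kb	SOR	0.3898
Fielder	cds	IP	0.0449
Fielder	cds	OP	0.1209
Fielder	cds	SOR	0.0300
Fielder	gene_body	IP	0.0532
Fielder	gene_body	OP	0.2120
Fielder	gene_body	SOR	0.0603
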