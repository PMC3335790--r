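entry_id	chain_id	receptor_id	ligand_class	notes
1U19	A	brh	inverse_agonist	11-cis-retinal
2Z73	A	srh	inverse_agonist	11-cis-retinal
2RH1	A	b2	inverse_agonist	carazolol; T4L
2VT4	B	b1	antagonist	cyanopindolol
3EML	A	A2A	antagonist	ZM241385; T4L
3ODU	A	CXCR4	antagonist	IT1t; T4L
3PBL	A	D3	antagonist	eticlopride; T4L
3RZE	A	H1	antagonist	doxepin; T4L
3UON	A	M2	antagonist	QNB; T4L
3V2Y	A	S1P1	antagonist	ML056; T4L
3PQR	A	brh	agonist	all-trans-retinal
3PXO	A	brh	agonist	all-trans-retinal
3SN6	R	b2	agonist	BI-167107; Gs and Nb35 bound
3QAK	A	A2A	agonist	UK-432097; T4L
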