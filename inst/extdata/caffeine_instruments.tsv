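exposure	rsid	effect_allele	other_allele	beta	se	pvalue	eaf	gene_label
plasma_caffeine	rs4410790	T	C	0.109	0.015	1.80e-10	0.36	AHR
plasma_caffeine	rs2472297	C	T	0.150	0.016	1.00e-17	0.73	CYP1A2
caffeine_intake	rs4410790	C	T	0.150	0.017	2.36e-19	0.38	AHR
caffeine_intake	rs2470893	T	C	0.120	0.016	5.15e-14	0.31	CYP1A2
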