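exposure	outcome	scale	estimate	ci_low	ci_high	pvalue	known_typo
plasma_caffeine	log_eGFRcrea	beta	-0.025	-0.028	-0.022	4.1e-53	FALSE
plasma_caffeine	log_eGFRcyst	beta	-0.018	-0.025	-0.011	1.6e-6	FALSE
plasma_caffeine	log_UACR	beta	-0.179	-0.215	-0.143	1.7e-22	FALSE
plasma_caffeine	urinary_sodium	beta	0.149	0.115	0.170	1.6e-24	TRUE
plasma_caffeine	BUN	beta	0.04	0.025	0.055	1.9e-7	FALSE
caffeine_intake	log_eGFRcrea	beta	0.020	0.014	0.015	1.8e-11	TRUE
caffeine_intake	log_eGFRcyst	beta	0.013	0.03	0.02	0.01	TRUE
caffeine_intake	log_UACR	beta	0.163	0.120	0.206	1.6e-3	TRUE
caffeine_intake	CKD	odds_ratio	0.84	0.75	0.94	0.003	FALSE
caffeine_intake	urinary_sodium	beta	-0.125	-0.158	-0.093	2.6e-14	FALSE
caffeine_intake	BUN	beta	-0.034	-0.064	-0.005	0.023	FALSE
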