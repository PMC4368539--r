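pattern	region	fraction	band	protein	note
RL_EQ_NL	hippocampus	membrane	within	CDK5	
RL_EQ_NL	hippocampus	nuclear	beyond	TRKA	
RL_EQ_NL	hippocampus	cytosolic	beyond	ELK	
RL_EQ_NL	hippocampus	cytosolic	beyond	pNR2B	
RL_EQ_NL	hippocampus	membrane	beyond	CaNA	
RL_EQ_NL	cortex	nuclear	within	AKT	
RL_EQ_NL	cortex	cytosolic	within	CASP3	
RL_EQ_NL	cortex	membrane	within	CAMKII	
RL_EQ_NL	cortex	cytosolic	beyond	TRKA	
RL_EQ_NL	cortex	cytosolic	beyond	pPKCAB	printed as pPKCAB; Table 3 spelling pPKCA
RL_EQ_NL	cortex	cytosolic	beyond	pBRAF	
BTM_COMP	hippocampus	nuclear	beyond	NUMB	
BTM_PLUS_RL	hippocampus	nuclear	within	pJNK	
BTM_PLUS_RL	cortex	nuclear	within	CaNA	
BTM_PLUS_RL	cortex	nuclear	beyond	ERBB4	
BTM_PLUS_RL	cortex	nuclear	beyond	ubiquitin	printed lower case; Table 3 spelling Ubiquitin
BTM_PLUS_RL	cortex	cytosolic	beyond	GAD2	
BTM_PLUS_RL	cortex	membrane	beyond	TIAM1	
RL_PLUS_B	hippocampus	nuclear	within	pEIF4B	
RL_PLUS_B	hippocampus	nuclear	within	TH	
RL_PLUS_B	hippocampus	membrane	within	NR2B	
RL_PLUS_B	hippocampus	nuclear	beyond	pERK	
RL_PLUS_B	hippocampus	cytosolic	beyond	pJNK	
RL_PLUS_B	hippocampus	cytosolic	beyond	ERK	
RL_PLUS_B	cortex	cytosolic	within	AKT	
RL_PLUS_B	cortex	membrane	within	SYP	
RL_PLUS_B	cortex	cytosolic	beyond	CTNNB1	
RL_PLUS_B	cortex	cytosolic	beyond	RSK	
RL_PLUS_B	cortex	cytosolic	beyond	RCAN1	
RL_PLUS_B	cortex	cytosolic	beyond	MTOR	
RL_PLUS_B_PLUS_BTM	hippocampus	nuclear	within	Ubiquitin	
RL_PLUS_B_PLUS_BTM	hippocampus	cytosolic	within	JNK	
RL_PLUS_B_PLUS_BTM	hippocampus	cytosolic	within	pP70S6	
RL_PLUS_B_PLUS_BTM	hippocampus	nuclear	beyond	SOD1	
RL_PLUS_B_PLUS_BTM	hippocampus	nuclear	beyond	ERBB4	
RL_PLUS_B_PLUS_BTM	hippocampus	nuclear	beyond	PP2A	
RL_PLUS_B_PLUS_BTM	hippocampus	cytosolic	beyond	IL1B	
RL_PLUS_B_PLUS_BTM	cortex	nuclear	within	ARC	
RL_PLUS_B_PLUS_BTM	cortex	nuclear	within	pS6	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	within	pMEK	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	within	RAPTOR	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	within	pNR2A	
RL_PLUS_B_PLUS_BTM	cortex	nuclear	beyond	pPKCAB	printed as pPKCAB; Table 3 spelling pPKCA
RL_PLUS_B_PLUS_BTM	cortex	nuclear	beyond	IL1B	
RL_PLUS_B_PLUS_BTM	cortex	nuclear	beyond	pGSK3BS9	
RL_PLUS_B_PLUS_BTM	cortex	nuclear	beyond	SNCA	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	pNUMB	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	IL1B	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	S6	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	pGSK3B-T216	printed with hyphen; Table 3 spelling pGSK3BT216
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	pCASP9	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	Ubiquitin	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	pERK	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	P70S6	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	BAX	
RL_PLUS_B_PLUS_BTM	cortex	cytosolic	beyond	TAU	
RL_PLUS_B_PLUS_BTM	cortex	membrane	beyond	pERK	
RL_PLUS_B_PLUS_BTM	cortex	membrane	beyond	TRKA	
RL_PLUS_B_PLUS_BTM	cortex	membrane	beyond	pNUMB	
RL_PLUS_B_PLUS_BTM	cortex	membrane	beyond	CTNNB1	
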