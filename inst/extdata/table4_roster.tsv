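pattern	region	fraction	band	protein	note
FL_EQ_NL	hippocampus	nuclear	within	CaNA	
FL_EQ_NL	hippocampus	nuclear	within	H3AcK9	
FL_EQ_NL	hippocampus	cytosolic	within	RAPTOR	
FL_EQ_NL	hippocampus	cytosolic	within	BAD	
FL_EQ_NL	hippocampus	membrane	within	NR1	
FL_EQ_NL	hippocampus	membrane	within	pNR1	
FL_EQ_NL	hippocampus	nuclear	beyond	pSRC	
FL_EQ_NL	hippocampus	cytosolic	beyond	CDK5	
FL_EQ_NL	hippocampus	cytosolic	beyond	EGR1	
FL_EQ_NL	hippocampus	cytosolic	beyond	pERK	
FL_EQ_NL	hippocampus	cytosolic	beyond	MTOR	
FL_EQ_NL	hippocampus	cytosolic	beyond	pNR1	
FL_EQ_NL	hippocampus	cytosolic	beyond	pNR2A	
FL_EQ_NL	hippocampus	membrane	beyond	RCAN1	
FL_EQ_NL	cortex	nuclear	within	EGR1	
FL_EQ_NL	cortex	nuclear	within	H3MeK4	
FL_EQ_NL	cortex	nuclear	within	nNOS	
FL_EQ_NL	cortex	nuclear	within	SOD1	
FL_EQ_NL	cortex	membrane	within	FYN	
FL_EQ_NL	cortex	nuclear	beyond	BRAF	
FL_EQ_NL	cortex	nuclear	beyond	pERK	
FL_EQ_NL	cortex	nuclear	beyond	P38	
FL_EQ_NL	cortex	cytosolic	beyond	BDNF	
FL_EQ_NL	cortex	membrane	beyond	pCAMKII	
B_COMP	hippocampus	nuclear	within	JNK	
B_COMP	hippocampus	nuclear	within	pAKT	
B_COMP	hippocampus	nuclear	within	pGSK3BS9	
B_COMP	hippocampus	nuclear	within	pMEK	
B_COMP	hippocampus	nuclear	within	pPKCAB	printed as pPKCAB; Table 3 spelling pPKCA
B_COMP	hippocampus	nuclear	within	RSK	
B_COMP	hippocampus	nuclear	beyond	ELK	
B_COMP	hippocampus	nuclear	beyond	P70S6	
B_COMP	hippocampus	nuclear	beyond	PKCA	
B_COMP	hippocampus	nuclear	beyond	pCFOS	
B_COMP	hippocampus	nuclear	beyond	pMTOR	
B_COMP	hippocampus	nuclear	beyond	pRSK	
B_COMP	hippocampus	cytosolic	beyond	AKT	
B_COMP	hippocampus	cytosolic	beyond	P70S6	
B_COMP	hippocampus	membrane	beyond	BDNF	
B_COMP	cortex	cytosolic	within	pAKT	
B_COMP	cortex	cytosolic	within	pNR1	
B_COMP	cortex	cytosolic	within	pRSK	
B_COMP	cortex	membrane	within	pGluR2	
B_COMP	cortex	nuclear	beyond	CDK5	
B_COMP	cortex	nuclear	beyond	pNUMB	
B_COMP	cortex	cytosolic	beyond	ELK	
B_COMP	cortex	cytosolic	beyond	JNK	
B_COMP	cortex	cytosolic	beyond	TIAM1	
B_PLUS_FL	hippocampus	nuclear	within	BRAF	
B_PLUS_FL	hippocampus	nuclear	within	FYN	
B_PLUS_FL	hippocampus	cytosolic	within	NR2B	
B_PLUS_FL	hippocampus	cytosolic	within	pBRAF	
B_PLUS_FL	hippocampus	cytosolic	within	pMTOR	
B_PLUS_FL	hippocampus	membrane	within	NR2A	
B_PLUS_FL	hippocampus	nuclear	beyond	H3AcK18	
B_PLUS_FL	hippocampus	nuclear	beyond	GSK3B	
B_PLUS_FL	hippocampus	cytosolic	beyond	pMEK	
B_PLUS_FL	hippocampus	membrane	beyond	pERK	
B_PLUS_FL	cortex	nuclear	within	DYRK1A	
B_PLUS_FL	cortex	nuclear	within	ITSN1	
B_PLUS_FL	cortex	cytosolic	within	P70S6	
B_PLUS_FL	cortex	cytosolic	beyond	NR2B	
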