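code	group_a	group_b	description
B	t-SC-sal	c-SC-sal	initial genotype differences
B-tm	t-SC-mem	t-SC-sal	memantine effect on trisomic baseline
B-cm	c-SC-mem	c-SC-sal	memantine effect on control baseline
B-tm-cs	t-SC-mem	c-SC-sal	memantine-treated trisomic baseline vs saline control baseline
NL	c-CS-sal	c-SC-sal	CFC training effect in saline-injected controls
FL	t-CS-sal	t-SC-sal	CFC training effect in saline-injected trisomics
RL	t-CS-mem	t-SC-mem	CFC training effect in memantine-injected trisomics
RL-FL	t-CS-mem	t-CS-sal	endpoint: rescued vs failed learning
RL-NL	t-CS-mem	c-CS-sal	endpoint: rescued vs normal learning
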