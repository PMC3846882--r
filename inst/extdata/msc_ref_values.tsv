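ipi	uniprot	gene_symbol	ref_AIMP1	ref_AIMP2	ref_KARS
IPI00006252	Q12904	AIMP1	4.73	1.19	1.18
IPI00011916	Q13155	AIMP2	0.69	3.28	1.65
IPI00216951	P14868	DARS	0.65	0.72	0.68
IPI00003588	O43324	EEF1E1	0.44	0.18	0.84
IPI00013452	P07814	EPRS	0.55	0.84	0.69
IPI00644127	P41252	IARS	1.06	1.60	1.39
IPI00014238	Q15046	KARS	0.80	0.75	3.75
IPI00103994	Q9P2J5	LARS	0.89	1.22	0.95
IPI00008240	P56192	MARS	0.35	0.38	0.39
IPI00925046	P47897	QARS	2.95	2.07	1.51
IPI00004860	P54136	RARS	1.62	1.04	0.73
IPI00328082	A2RTX5	TARSL2	0.57	0.43	0.53
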