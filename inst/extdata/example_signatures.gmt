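SIN3A_complex_core	illustrative example only, not the study signature	SIN3A	HDAC1	HDAC2	SAP130	SAP30	SAP18	SUDS3	ARID4A	ARID4B	RBBP4	RBBP7	ING1	ING2	BRMS1	FAM60A
CoREST_core	illustrative example only	RCOR1	RCOR2	RCOR3	KDM1A	HDAC1	HDAC2	HMG20B	PHF21A	GSE1
NuRD_core	illustrative example only	CHD3	CHD4	HDAC1	HDAC2	MTA1	MTA2	MTA3	MBD2	MBD3	GATAD2A	GATAD2B	RBBP4	RBBP7
G1S	illustrative G1/S phase list	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	PCNA	RRM1	RRM2	CDC6	CDC45	GINS2	SLBP	TYMS	FEN1	HELLS	UNG	POLA1	CHAF1B	E2F8
G2M	illustrative G2/M phase list	CDK1	TOP2A	CCNB1	CCNB2	BUB1	BUB1B	AURKA	AURKB	PLK1	MKI67	CENPA	CENPE	CENPF	UBE2C	BIRC5	TPX2	KIF11	KIF23	NUSAP1	ANLN
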