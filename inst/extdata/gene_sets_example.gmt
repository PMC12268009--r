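TCA_cycle	synthetic example set	CS	SDHA	IDH2	FH	MDH2
glycolysis	synthetic example set	PGK1	LDHA	ENO3	GPD1	PFKM	TPI1
ox_stress	synthetic example set	HMOX1	MT1A	MT1B	ATF3	JUN
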