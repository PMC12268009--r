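protein_id	pct_type1	pct_type2a	pct_type2x
MYH7	78.0	14.0	8.0
MYL3	74.5	16.5	9.0
MYL2	71.0	19.0	10.0
TNNT1	69.5	20.5	10.0
TNNI1	68.0	22.0	10.0
ATP2A2	66.0	24.0	10.0
MYH2	12.0	62.0	26.0
MYH1	10.0	28.0	62.0
MYBPH	14.0	48.0	38.0
MYBPC2	15.0	50.0	35.0
ACTN3	11.0	35.0	54.0
TNNT3	13.0	46.0	41.0
TNNI2	12.5	47.5	40.0
PVALB	9.0	30.0	61.0
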