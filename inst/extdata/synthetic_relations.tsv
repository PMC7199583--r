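regulator	target	polarity	disease_direction	n_refs
PPARG	COL1A1	-|	up_in_disease	68
PPARG	SPP1	-|	up_in_disease	55
PPARG	CXCL14	-|	up_in_disease	23
PPARG	MMP9	-|	up_in_disease	142
PPARG	CCNB1	-|	up_in_disease	31
PPARG	IL1B	-|	up_in_disease	120
PPARG	PTGS2	-|	up_in_disease	98
PPARG	TNF	-|	up_in_disease	160
PPARG	VEGFA	-|	up_in_disease	75
PPARG	MKI67	-|	up_in_disease	28
PPARG	TOP2A	-|	up_in_disease	22
PPARG	MMP2	-|	up_in_disease	64
PPARG	CXCL8	-|	up_in_disease	51
PPARG	CAV1	-+>	down_in_disease	40
PPARG	PTEN	-+>	down_in_disease	88
PPARG	FAS	-+>	down_in_disease	52
PPARG	MIR145	-+>	down_in_disease	36
PPARG	CDKN1A	-+>	down_in_disease	45
PPARG	ADIPOQ	-+>	down_in_disease	18
PPARG	IL1B	-|	promoter	9
PPARG	PTGS2	-|	promoter	6
PPARG	TNF	-|	promoter	5
PPARG	EDN1	-|	promoter	4
PPARG	CCR7	-|	promoter	3
PPARG	TLR2	-|	promoter	2
PPARG	NOS2	-|	promoter	4
PPARG	MIR145	-+>	inhibitor	2
PPARG	CDKN2A	-+>	inhibitor	2
PPARG	TIMP3	-+>	inhibitor	2
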