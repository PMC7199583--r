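regulator	target	polarity	disease_direction	n_refs
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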