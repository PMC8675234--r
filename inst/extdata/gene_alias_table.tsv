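alias	symbol
MLL2	KMT2D
MLL4	KMT2B
MLL	KMT2A
MLL3	KMT2C
WHSC1	NSD2
TNFRSF6	FAS
C2TA	CIITA
KIAA1045	PHF24
CXorf67	EZHIP
FAM46C	TENT5C
GPR98	ADGRV1
MYCL1	MYCL
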