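gene	role	known_changes	known_positions
TP53	tsg	R175H,R248Q,R273H	175,245,248,273,282
KRAS	oncogene	G12D,G12V,G13D	12,13,61
NRAS	oncogene	G12C,G12D,Q61K	12,13,61
PIK3CA	oncogene	E542K,E545K,H1047R,Y1021C,Y1021H,E418K	418,542,545,1021,1047
B2M	tsg
ARID1A	tsg
ARID1B	tsg
ARID2	tsg
SMARCA4	tsg
MLH1	tsg
MSH6	tsg
RNF43	tsg
APC	tsg
ACVR2A	tsg
PRDM2	tsg
JAK1	tsg
JAK2	tsg
PBRM1	tsg
CHEK2	tsg
ATR	tsg
BLM	tsg
PTEN	tsg
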