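block	stage	wildtype	mutant
T	T1	0	0
T	T2	9	0
T	T3	58	5
T	T4	32	3
N	N0	35	2
N	N1	38	3
N	N2	26	3
M	M0	53	1
M	M1	46	7
AJCC	I	6	0
AJCC	II	12	1
AJCC	III	32	0
AJCC	IV	49	7
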