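haplogroup	parent	defining_variants
ROOT		
L1	ROOT	C2484T,T8881C,C4574T
L2	ROOT	G10875A
L3	ROOT	A9052G,A5849G
M	L3	C12768T
N	L3	A4702G
R	N	T2235C,T1425C
R0	R	C5388T,A5969G,A7644G
U	R	A12967G
HV	R0	A13104G,C16210T
H	HV	T7473C,A11353G
H1	H	A7206G,T15877C,C4421T
H2	H	G7786A
H1a	H1	A16412G,G12497A
U5	U	T12615C
K	U	G15695A,A2945G,G13023A
M1	M	T2571C,A1195G
D	M	T1200C,T9095C
D4	D	G7177A
J	R	T11727C
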