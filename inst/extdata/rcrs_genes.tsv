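name	start	end	kind	orientation	complex
tRNA-Phe	577	647	tRNA	forward	none
RNR1	648	1601	rRNA	forward	none
tRNA-Val	1602	1670	tRNA	forward	none
RNR2	1671	3229	rRNA	forward	none
tRNA-Leu1	3230	3304	tRNA	forward	none
ND1	3307	4262	protein	forward	I
tRNA-Ile	4263	4331	tRNA	forward	none
tRNA-Gln	4329	4400	tRNA	reverse	none
tRNA-Met	4402	4469	tRNA	forward	none
ND2	4470	5511	protein	forward	I
tRNA-Trp	5512	5579	tRNA	forward	none
tRNA-Ala	5587	5655	tRNA	reverse	none
tRNA-Asn	5657	5729	tRNA	reverse	none
tRNA-Cys	5761	5826	tRNA	reverse	none
tRNA-Tyr	5826	5891	tRNA	reverse	none
COI	5904	7445	protein	forward	IV
tRNA-Ser1	7446	7514	tRNA	reverse	none
tRNA-Asp	7518	7585	tRNA	forward	none
COII	7586	8269	protein	forward	IV
tRNA-Lys	8295	8364	tRNA	forward	none
ATP8	8366	8572	protein	forward	V
ATP6	8527	9207	protein	forward	V
COIII	9207	9990	protein	forward	IV
tRNA-Gly	9991	10058	tRNA	forward	none
ND3	10059	10404	protein	forward	I
tRNA-Arg	10405	10469	tRNA	forward	none
ND4L	10470	10766	protein	forward	I
ND4	10760	12137	protein	forward	I
tRNA-His	12138	12206	tRNA	forward	none
tRNA-Ser2	12207	12265	tRNA	forward	none
tRNA-Leu2	12266	12336	tRNA	forward	none
ND5	12337	14148	protein	forward	I
ND6	14149	14673	protein	reverse	I
tRNA-Glu	14674	14742	tRNA	reverse	none
CYB	14747	15887	protein	forward	III
tRNA-Thr	15888	15953	tRNA	forward	none
tRNA-Pro	15956	16023	tRNA	reverse	none
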