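start	end	region	gene	strand
1	576	loop	CR	+
577	647	tRNA	TRNF	+
648	1601	rRNA	RNR1	+
1602	1670	tRNA	TRNV	+
1671	3229	rRNA	RNR2	+
3230	3304	tRNA	TRNL1	+
3305	3306	loop	NC1	+
3307	4262	coding	ND1	+
4263	4331	tRNA	TRNI	+
4329	4400	tRNA	TRNQ	-
4401	4401	loop	NC2	+
4402	4469	tRNA	TRNM	+
4470	5511	coding	ND2	+
5512	5579	tRNA	TRNW	+
5580	5586	loop	NC3	+
5587	5655	tRNA	TRNA	-
5656	5656	loop	NC4	+
5657	5729	tRNA	TRNN	-
5730	5760	loop	OLR	+
5761	5826	tRNA	TRNC	-
5827	5891	tRNA	TRNY	-
5892	5903	loop	NC5	+
5904	7445	coding	CO1	+
7446	7514	tRNA	TRNS1	-
7515	7517	loop	NC6	+
7518	7585	tRNA	TRND	+
7586	8269	coding	CO2	+
8270	8294	loop	NC7	+
8295	8364	tRNA	TRNK	+
8365	8365	loop	NC8	+
8366	8572	coding	ATP8	+
8527	9207	coding	ATP6	+
9208	9990	coding	CO3	+
9991	10058	tRNA	TRNG	+
10059	10404	coding	ND3	+
10405	10469	tRNA	TRNR	+
10470	10766	coding	ND4L	+
10760	12137	coding	ND4	+
12138	12206	tRNA	TRNH	+
12207	12265	tRNA	TRNS2	+
12266	12336	tRNA	TRNL2	+
12337	14148	coding	ND5	+
14149	14673	coding	ND6	-
14674	14742	tRNA	TRNE	-
14743	14746	loop	NC9	+
14747	15887	coding	CYB	+
15888	15953	tRNA	TRNT	+
15954	15955	loop	NC10	+
15956	16023	tRNA	TRNP	-
16024	16569	loop	CR	+
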