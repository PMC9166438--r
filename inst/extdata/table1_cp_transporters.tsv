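# Top 20 plasma-membrane transporters and pumps in rat choroid plexus,
# with each gene's rank in the FACS epithelial-cell sample and in the
# female choroid plexus sample.
Gene	Alias	TPM	Rank	FACS_rank	Female_rank
SLC22A17	BOCT	2396	1	1	1
ATP1B1	NKA.B1	1553	2	2	2
FXYD1	FXYD1	1076	3	3	3
SLC4A5	NBCE2	881	4	7	4
SLC4A2	AE2	638	5	5	5
SLC13A4	SUT1	627	6	6	7
ATP1A1	NKA.A1	623	7	4	6
SLC31A1	CTR1	469	8	9	8
ATP2B3	PMCA3	396	9	15	11
SLC16A2	MCT8	380	10	13	9
SLC4A10	NCBE	325	11	26	12
SLCO1C1	BSAT1	301	12	12	13
SLC38A3	SNAT3	298	13	8	10
SLC12A2	NKCC1	268	14	17	14
ATP1B2	NKA.B2	248	15	18	17
ATP11A	ATP11A	242	16	23	19
ATP1B3	NKA.B3	236	17	10	15
TMEM30A	TMEM30A	229	18	21	16
SLC12A4	KCC1	192	19	11	18
SLC20A2	PIT2	182	20	16	21
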