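# Top 20 plasma-membrane water and ion channels in rat choroid plexus,
# with FACS-sample and female-sample ranks.
Gene	Alias	TPM	Rank	FACS_rank	Female_rank
KCNJ13	Kir7.1	1372	1	2	1
AQP1	AQP1	721	2	1	2
KCNK1	TWIK-1	158	3	3	3
TRPM3	TRPM3	137	4	7	4
TRPV4	TRPV4	92	5	4	5
ORAI1	ORAI1	62	6	5	6
MCOLN1	TRPML1	37	7	6	7
CLCN3	ClC-3	34	8	15	9
KCNJ14	Kir2.4	31	9	55	8
TRPM7	TRPM7	30	10	18	12
KCNQ1	KV7.1	30	11	9	10
P2RX6	P2X6	26	12	8	11
PKD2	TRPP2	25	13	13	13
KCNA1	KV1.1	18	14	43	20
ORAI3	ORAI3	17	15	10	14
KCNS1	KV9.1	16	16	11	15
KCNC3	KV3.3	15	17	21	18
CLCN4	ClC-4	14	18	23	19
GRIK5	GluK5	13	19	12	16
GJB2	Cx26	12	20	14	22
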