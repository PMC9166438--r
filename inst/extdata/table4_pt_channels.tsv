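# Top 20 plasma-membrane water and ion channels in rat kidney proximal
# tubule, with choroid plexus ranks (NA below the 0.5 TPM cutoff).
Gene	Alias	TPM	Rank	CP_rank
KCNJ16	Kir5.1	235	1	NA
KCNJ1	Kir1.1	89	2	NA
AQP1	AQP1	48	3	2
TRPV1	TRPV1	15	4	NA
GJB2	Cx26	13	5	20
AQP3	AQP3	10	6	NA
AQP7	AQP7	9	7	NA
TRPM7	TRPM7	9	8	10
GABRP	GABARpi	9	9	NA
MCOLN1	TRPML1	8	10	7
MCOLN3	TRPML3	7	11	NA
CLCN4	ClC-4	4	12	18
CFTR	CFTR	4	13	NA
CLCNKA	ClCK1	3	14	NA
GJB1	Cx32	3	15	NA
KCNJ15	Kir4.2	2	16	85
CHRNB1	ACHB	2	17	47
PANX2	Panx2	2	18	40
P2RX4	P2X4	2	19	28
GJA1	Cx43	2	20	27
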