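# Top 20 plasma-membrane transporters and pumps in rat kidney proximal
# tubule, with each gene's rank in the choroid plexus sample (NA when the
# gene is transcribed below the 0.5 TPM cutoff there).
Gene	Alias	TPM	Rank	CP_rank
SLC7A13	XAT2	7344	1	NA
SLC3A1	NBAT	3113	2	98
SLC16A4	MCT5	993	3	NA
SLC13A1	NAS1	384	4	NA
FXYD2	FXYD2	359	5	NA
PDZD11	PDZD11	279	6	30
ABCG2	BCRP	164	7	209
SLC17A3	NPT4	148	8	NA
SLC5A12	SMCT2	147	9	NA
SLC31A1	CTR1	136	10	8
SLC51B	OSTB	131	11	NA
ATP1B1	NKA.B1	98	12	2
MAGT1	MAGT1	72	13	58
SLC34A1	NPT2	67	14	NA
SLC16A12	MCT12	45	15	42
SLC22A6	OAT1	29	16	NA
SLC22A2	OCT2	25	17	NA
TMEM30A	TMEM30A	24	18	18
SLC15A2	PEPT2	22	19	87
SLC5A2	SGLT2	22	20	137
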