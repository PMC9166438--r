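# Reconstructed default grouping of the SLC solute-carrier families into
# 11 substrate supercategories. This is configuration data, not code:
# replace it with your own two-column (family, supercategory) table to
# change the grouping.
family	supercategory
SLC1	amino_acid_neurotransmitter
SLC2	sugar
SLC3	amino_acid_neurotransmitter
SLC4	electrolyte_bicarbonate
SLC5	sugar
SLC6	amino_acid_neurotransmitter
SLC7	amino_acid_neurotransmitter
SLC8	electrolyte_bicarbonate
SLC9	electrolyte_bicarbonate
SLC10	large_anion
SLC11	metal
SLC12	electrolyte_bicarbonate
SLC13	large_anion
SLC14	other
SLC15	peptide
SLC16	large_anion
SLC17	large_anion
SLC18	other
SLC19	vitamin
SLC20	other
SLC22	organic_ion
SLC23	vitamin
SLC24	electrolyte_bicarbonate
SLC25	other
SLC26	electrolyte_bicarbonate
SLC27	lipid
SLC28	nucleoside_nucleotide
SLC29	nucleoside_nucleotide
SLC30	metal
SLC31	metal
SLC32	amino_acid_neurotransmitter
SLC33	other
SLC34	other
SLC35	nucleoside_nucleotide
SLC36	amino_acid_neurotransmitter
SLC37	sugar
SLC38	amino_acid_neurotransmitter
SLC39	metal
SLC40	metal
SLC41	metal
SLC42	other
SLC43	amino_acid_neurotransmitter
SLC44	lipid
SLC45	sugar
SLC46	vitamin
SLC47	other
SLC48	other
SLC49	other
SLC50	sugar
SLC51	lipid
SLC52	vitamin
SLC53	other
SLC54	other
SLC55	other
SLC56	other
SLC57	other
SLC58	other
SLC59	lipid
SLC60	sugar
SLC61	other
SLC62	other
SLC63	other
SLC64	other
SLC65	other
SLC66	other
SLCO	large_anion
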