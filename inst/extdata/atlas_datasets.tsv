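dataset	n_patients	n_cells
GSE161529	33	224823
Lambrechts_2021	31	78549
GSE176078	26	99876
GSE248288	14	48553
Lambrechts_2020	14	40665
E-MTAB-10607	12	97301
GSE225600	4	27490
GSE148673	4	3943
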