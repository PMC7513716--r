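region	n_accessions	n_structure_carriers	n_haplotypes	n_region_specific_haplotypes	n_orf79_carriers	n_orf79_alleles	n_region_specific_alleles
SA-I	37	12	5	3	19	3	0
SA-II	38	8	5	3	12	5	1
EA	79	19	5	3	21	6	4
SEA	67	5	5	2	7	4	1
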