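haplotype	SA-I	SA-II	EA	SEA
H1	3	1	0	1
H2	0	1	0	0
H3	0	0	0	1
H4	0	1	0	0
H5	1	0	0	0
H6	4	0	0	0
H8	0	0	1	0
H9	0	0	2	0
H10	0	0	2	0
H11	0	0	5	1
H12	0	3	0	0
H13	3	0	0	0
H14	1	2	0	0
H15	0	0	0	1
H16	0	0	9	1
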