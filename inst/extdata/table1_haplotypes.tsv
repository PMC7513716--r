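haplotype	atp6	fs	ncs	orf79	n_rufipogon	n_sativa
H1	atp6	fs1a	ncs1-BT	orf79a	5	1
H2	atp6	fs1a	ncs1-c	orf79a	1	20
H3	atp6	fs1a	ncs1-a	orf79a	1	0
H4	atp6	fs1a	ncs1-a	orf79b	1	4
H5	atp6	fs1a	ncs1-a-SV	orf79a	1	0
H6	atp6	fs1a	ncs1-d	orf79a	4	4
H7	atp6	fs1b	ncs1-d	orf79a	0	1
H8	atp6	fs1a	ncs1-e1	orf79c	1	0
H9	atp6	fs1a	ncs1-e1	orf79f	2	0
H10	atp6	fs1a	ncs3-a	orf79j	2	0
H11	atp6	fs1a	ncs3-HL	orf79k	6	0
H12	atp6	fs1a	ncs3-b1	orf79k	3	0
H13	atp6	fs1a	ncs3-b2-SV	orf79k	3	0
H14	atp6	fs1a	ncs2-a	orf79g	3	0
H15	atp6	fs1a	ncs2-c	orf79i	1	0
H16	atp6	fs2	ncs1-e2	orf79e	10	0
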