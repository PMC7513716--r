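pos	kind	H1	H2	H3	H4	H5	H6	H7	H8	H9	H10	H11	H12	H13	H14	H15	H16
1008	SNP	T	T	T	T	T	T	T	T	T	T	T	T	T	T	T	A
1011-1115	Sub	105	105	105	105	105	105	105	105	105	105	105	105	105	105	105	49
1063	SNP	C	C	C	C	C	C	G	C	C	C	C	C	C	C	C	C
1123	SNP	T	T	T	T	C	T	T	T	T	T	T	T	T	T	T	T
1125	Ins												T	T			
1128-1136	Sub	9	9	9	9	12	9	9	9	9	9	9	9	9	9	9	9
1149	SNP	A	A	A	A	A	A	A	A	A	A	A	A	A	G	G	A
1153	SNP	A	A	A	A	A	A	A	A	A	G	G	G	G	A	A	A
1159-1203	Sub	45	45	45	45	45	45	45	45	45	51	51	51	53	46	55	45
1206	SNP	A	A	A	A	A	A	A	C	C	C	C	C	C	C	C	C
1210	SNP	T	T	T	T	T	T	T	T	T	T	T	T	T	C	T	T
1214	Ins			4	4	4											
1214	SNP	A	A	A	A	A	T	T	A	A	A	C	C	C	A	A	C
1215	SNP	T	T	T	T	T	T	T	T	T	T	T	T	T	T	G	T
1218	SNP	T	T	T	T	T	T	T	T	T	T	T	T	C	C	T	T
1219	SNP	G	G	G	G	G	G	G	G	G	G	G	G	C	G	G	G
1220	SNP	C	T	C	C	C	C	C	C	C	C	C	C	C	C	C	C
1225	SNP	G	G	G	G	G	G	G	G	G	A	A	A	A	A	A	G
1234	SNP	G	G	G	G	G	G	G	G	G	C	C	C	C	G	G	G
1363	SNP	A	A	A	A	A	A	A	A	A	T	T	T	T	A	G	C
1367	SNP	A	A	A	C	A	A	A	C	C	A	A	A	A	A	A	C
1368	SNP	A	A	A	A	A	A	A	T	T	C	C	C	C	A	A	T
1399	SNP	C	C	C	C	C	C	C	C	T	C	T	T	T	C	C	C
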