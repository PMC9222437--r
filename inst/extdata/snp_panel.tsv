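snp_id	alias	position	allele1	allele2	codon	aa1	aa2
rs94930	rs949930	1	A	G	151	NA	NA
rs713	NA	2	A	C	153	M	L
rs731614	NA	3	C	G	NA	NA	NA
rs5986963	NA	4	A	G	171	I	V
rs5986964	NA	5	T	G	171	NA	NA
rs149897670	NA	6	C	T	174	A	V
rs145009674	NA	7	A	G	178	I	V
rs155715655	NA	8	G	T	180	A	S
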