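##fileformat=VCFv4.2
##source=trioscan packaged fixture stub panel (synthetic; see README.md)
##reference=GRCh37
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010	S0011	S0012	S0013	S0014	S0015	S0016	S0017	S0018	S0019	S0020
1	1000000	rs687289	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
1	1060000	rs532436	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
2	1000000	rs763101897	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
2	1060000	rs2008206	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
3	1000000	rs367882553	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
3	1060000	rs6875225	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
4	1000000	rs139280910	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
4	1060000	rs265369	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
5	1000000	rs6072799	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
5	1060000	rs6030381	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
6	1000000	rs11371772	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
6	1060000	rs12488603	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
7	1000000	rs552913575	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
7	1060000	rs7694663	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
8	1000000	rs146139464	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
8	1060000	rs2675124	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
9	1000000	rs61885278	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
9	1060000	rs2716449	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
10	1000000	rs1467463821	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
10	1060000	rs1432523	A	G	.	PASS	.	GT	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0
11	1000000	rs4683988	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
11	1060000	rs2593865	A	G	.	PASS	.	GT	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1
12	1000000	rs575866680	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
12	1060000	rs56258049	A	G	.	PASS	.	GT	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0	0|1	0|0	1|0
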