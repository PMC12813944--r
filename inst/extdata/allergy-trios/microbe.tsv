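rsid	chrom	pos	effect_allele	pvalue	trait	study_id
rs687289	1	1000000	G	8.95E-14	Bifidobacterium bifidum	MB-GWAS-01
rs763101897	2	1000000	A	5.33E-07	Ruminococcus gnavus	MB-GWAS-02
rs367882553	3	1000000	T	5.94E-07	Dorea longicatena	MB-GWAS-03
rs139280910	4	1000000	C	7.2E-09	Bifidobacterium angulatum	MB-GWAS-04
rs6072799	5	1000000	G	5.52E-07	Bifidobacterium angulatum	MB-GWAS-05
rs11371772	6	1000000	A	3.26E-07	Neisseria gonorrhoeae	MB-GWAS-06
rs552913575	7	1000000	T	7.73E-07	Granulicatella adiacens	MB-GWAS-07
rs146139464	8	1000000	C	7.45E-07	Eggerthella lenta	MB-GWAS-08
rs61885278	9	1000000	G	3.5E-08	Prevotella buccae	MB-GWAS-09
rs1467463821	10	1000000	A	3.60E-07	Megasphaera micronuciformis	MB-GWAS-10
rs4683988	11	1000000	T	8.79E-07	Bacteroides clarus	MB-GWAS-11
rs575866680	12	1000000	C	5.18E-08	Megasphaera micronuciformis	MB-GWAS-12
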