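rsid	chrom	pos	effect_allele	pvalue	trait	study_id
rs532436	1	1060000	A	7.69E-13	Campesterol	MT-GWAS-01
rs2008206	2	1060000	G	5.03E-06	Succinylcarnitine	MT-GWAS-02
rs6875225	3	1060000	C	9.08E-06	4-Cholesten-3-one	MT-GWAS-03
rs265369	4	1060000	T	1.24E-07	Octadecanedioate	MT-GWAS-04
rs6030381	5	1060000	A	1.97E-07	Octanoylcarnitine	MT-GWAS-05
rs12488603	6	1060000	G	9.86E-06	N-oleoyltaurine	MT-GWAS-06
rs7694663	7	1060000	C	8.91E-06	Isoeugenol sulfate	MT-GWAS-07
rs2675124	8	1060000	T	4.75E-06	3-Phenylpropionate	MT-GWAS-08
rs2716449	9	1060000	A	1.06E-06	Choline phosphate	MT-GWAS-09
rs1432523	10	1060000	G	2.61E-06	Lactosyl-N-behenoyl-sphingosine	MT-GWAS-10
rs2593865	11	1060000	C	2.32E-08	Glycosyl ceramide	MT-GWAS-11
rs56258049	12	1060000	T	5.81E-06	N-acetyl-aspartyl-glutamate	MT-GWAS-12
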