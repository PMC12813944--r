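1	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "ABO"; gene_name "ABO"; gene_biotype "protein_coding";
2	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "SYN3"; gene_name "SYN3"; gene_biotype "protein_coding";
3	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "CAMK4"; gene_name "CAMK4"; gene_biotype "protein_coding";
4	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "LAMA2"; gene_name "LAMA2"; gene_biotype "protein_coding";
5	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "PTPRT"; gene_name "PTPRT"; gene_biotype "protein_coding";
6	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "SLC9A9"; gene_name "SLC9A9"; gene_biotype "protein_coding";
7	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "TENM3"; gene_name "TENM3"; gene_biotype "protein_coding";
8	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "AGAP1"; gene_name "AGAP1"; gene_biotype "protein_coding";
9	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "LUZP2"; gene_name "LUZP2"; gene_biotype "protein_coding";
10	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "PDE1A"; gene_name "PDE1A"; gene_biotype "protein_coding";
11	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "ROBO2"; gene_name "ROBO2"; gene_biotype "protein_coding";
12	trioscan_fixture	gene	950000	1100000	.	+	.	gene_id "SPOCK3"; gene_name "SPOCK3"; gene_biotype "protein_coding";
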