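entity	class	trait	provenance
ABO	gene	Allergic diseases (asthma, rhinitis, and eczema)	gwas_catalog-like
CAMK4	gene	Asthma	gwas_catalog-like
LAMA2	gene	Asthma	gwas_catalog-like
PTPRT	gene	Asthma	gwas_catalog-like
SLC9A9	gene	Asthma	gwas_catalog-like
TENM3	gene	Asthma	gwas_catalog-like
Ruminococcus gnavus	microbe	Allergic diseases (asthma, rhinitis, and eczema)	gutmdisorder-like
Eggerthella lenta	microbe	Eczema	gutmdisorder-like
Prevotella buccae	microbe	Eczema	gutmdisorder-like
Megasphaera micronuciformis	microbe	Eczema	gutmdisorder-like
Bacteroides clarus	microbe	Eczema	gutmdisorder-like
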