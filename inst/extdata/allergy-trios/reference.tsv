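gene	condition	gene_function	microbe_snp_location	metab_snp_location
ABO	Allergic diseases (asthma, rhinitis, and eczema)	Glycosphingolipid biosynthesis	intron	intron
SYN3	Allergic diseases (asthma, rhinitis, and eczema)	Neurotransmitter release and synaptic function	intron	intron
CAMK4	Asthma	Calcium-dependent signaling	intron	intron
LAMA2	Asthma	Tissue structure scaffolding	intron	intron
PTPRT	Asthma	Regulates cellular processes including growth and differentiation	intron	intron
SLC9A9	Asthma	A sodium/hydrogen exchanger/transporter	intron	intron
TENM3	Asthma	Neuronal development, immune regulation, and inflammation	intron	intron
AGAP1	Eczema	Intracellular trafficking, endocytosis	intron	intron
LUZP2	Eczema	Cytoskeleton and cellular shape	intergenic	intron
PDE1A	Eczema	Cellular signaling, regulating smooth muscle contraction	intron	intron
ROBO2	Eczema	Axon guidance	intron	intron
SPOCK3	Eczema	Regulating extracellular matrix and cell-matrix interactions	intron	intron
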