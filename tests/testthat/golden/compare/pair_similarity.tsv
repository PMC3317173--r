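gene_a	gene_b	region	rho	n	resampled	mode	policy	reason
geneA	geneB	promoter	-0.053769	1000	FALSE	coverage	resample_min	
geneA	geneB	coding	0.517129	1300	FALSE	coverage	resample_min	
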