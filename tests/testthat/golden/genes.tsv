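#gene_id	chrom	strand	start	end	species
geneA	chrS	+	1501	2800	synth
geneB	chrS	-	5801	7100	synth
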