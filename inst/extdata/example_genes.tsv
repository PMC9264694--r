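gene_id	chrom	tss	strand	start	end
GENE1	chr1	500000	+	500100	501500
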