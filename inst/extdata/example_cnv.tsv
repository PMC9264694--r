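individual	chrom	start	end	segment_mean
s01	chr1	1	1000000	0.35
s02	chr1	1	1000000	-0.2
s03	chr1	1	1000000	0.05
s04	chr1	1	1000000	0.02
s05	chr1	1	1000000	-0.04
s06	chr1	1	1000000	0.08
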