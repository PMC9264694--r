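##fileformat=VCFv4.2
##contig=<ID=chr1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24	s25	s26	s27	s28	s29	s30	s31	s32	s33	s34	s35	s36	s37	s38	s39	s40	s41	s42	s43	s44	s45	s46	s47	s48	s49	s50	s51	s52	s53	s54	s55	s56	s57	s58	s59	s60
chr1	5e+05	rs_causal	A	G	.	PASS	.	GT	0|0	1|0	1|0	1|0	0|0	0|0	0|0	0|0	1|0	0|0	0|0	0|0	0|0	1|0	1|0	1|0	1|1	0|0	1|0	1|0	1|0	1|0	0|0	0|0	1|0	1|0	1|0	1|0	1|1	0|0	1|1	1|0	1|0	1|0	0|0	1|1	1|1	1|1	1|0	1|0	0|0	1|0	0|0	1|1	1|1	1|1	0|0	1|1	1|0	0|0	1|1	0|0	1|0	1|1	1|0	0|0	0|0	1|0	1|0	1|0
chr1	500800	rs_func	A	G	.	PASS	.	GT	0|0	1|0	1|0	1|0	0|0	0|0	0|0	0|0	1|0	0|0	0|0	0|0	0|0	1|0	1|0	1|0	1|1	0|0	1|0	1|0	1|0	1|0	0|0	0|0	1|0	1|0	1|0	1|0	1|1	0|0	1|1	1|0	1|0	1|0	0|0	1|1	1|1	1|1	1|0	1|0	0|0	1|0	0|0	1|1	1|1	1|1	0|0	1|1	1|0	0|0	1|1	0|0	1|0	1|1	1|0	0|0	0|0	1|0	1|0	1|0
chr1	520000	rs_null1	A	G	.	PASS	.	GT	0|0	1|1	0|0	0|0	0|0	0|0	0|1	0|0	1|0	0|1	0|0	0|0	0|0	0|1	0|0	0|0	0|0	0|1	1|0	0|0	0|0	0|0	0|0	0|1	0|0	0|1	1|0	0|1	1|0	0|1	0|0	0|0	0|0	1|0	0|0	0|1	0|0	0|0	1|0	1|0	1|0	0|1	1|0	0|0	0|1	0|0	0|1	1|0	0|0	0|1	0|0	0|0	0|0	0|1	0|1	0|0	0|1	0|0	0|1	0|1
chr1	480000	rs_null2	A	G	.	PASS	.	GT	1|0	1|0	0|0	0|0	0|0	1|0	0|1	1|0	0|1	0|0	0|1	0|0	1|0	0|0	0|0	0|1	0|0	0|1	1|0	0|1	1|0	0|0	0|0	0|0	0|0	0|1	0|0	0|0	1|0	0|0	0|1	1|0	1|0	0|0	0|1	0|0	0|0	0|0	0|0	1|0	0|0	0|0	0|0	0|0	0|0	0|0	1|0	0|0	0|0	0|0	0|0	0|0	0|1	0|0	0|0	0|0	0|0	0|0	0|0	0|0
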