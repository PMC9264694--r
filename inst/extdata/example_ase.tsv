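individual	contig	position	variantID	refAllele	altAllele	refCount	altCount
s02	chr1	500800	rs_func	A	G	22	55
s03	chr1	500800	rs_func	A	G	16	61
s04	chr1	500800	rs_func	A	G	26	71
s09	chr1	500800	rs_func	A	G	23	58
s14	chr1	500800	rs_func	A	G	29	48
s15	chr1	500800	rs_func	A	G	30	47
s16	chr1	500800	rs_func	A	G	43	42
s19	chr1	500800	rs_func	A	G	22	55
s20	chr1	500800	rs_func	A	G	11	65
s21	chr1	500800	rs_func	A	G	18	72
s22	chr1	500800	rs_func	A	G	39	47
s25	chr1	500800	rs_func	A	G	9	81
s26	chr1	500800	rs_func	A	G	13	58
s27	chr1	500800	rs_func	A	G	16	49
s28	chr1	500800	rs_func	A	G	12	64
s32	chr1	500800	rs_func	A	G	26	46
s33	chr1	500800	rs_func	A	G	44	27
s34	chr1	500800	rs_func	A	G	28	67
s39	chr1	500800	rs_func	A	G	30	58
s40	chr1	500800	rs_func	A	G	13	69
s42	chr1	500800	rs_func	A	G	21	73
s49	chr1	500800	rs_func	A	G	29	52
s53	chr1	500800	rs_func	A	G	17	80
s55	chr1	500800	rs_func	A	G	29	61
s58	chr1	500800	rs_func	A	G	7	69
s59	chr1	500800	rs_func	A	G	26	76
s60	chr1	500800	rs_func	A	G	5	75
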