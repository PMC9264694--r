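gene_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24	s25	s26	s27	s28	s29	s30	s31	s32	s33	s34	s35	s36	s37	s38	s39	s40	s41	s42	s43	s44	s45	s46	s47	s48	s49	s50	s51	s52	s53	s54	s55	s56	s57	s58	s59	s60
GENE1	-1.1338	-2.0139	-0.4018	0.7064	0.499	0.1792	-0.2835	-0.183	1.5557	-1.3133	-1.0773	-0.5603	-2.4572	-0.9159	-1.1184	0.0482	-0.6302	-0.3627	-0.2671	-0.0948	-0.8245	-0.0525	-0.5704	0.5518	0.3614	-0.3593	-0.4546	-0.7791	2.0534	-1.0998	1.6593	-0.8432	0.2964	-1.2634	-0.407	0.2643	0.0818	0.5606	0.3799	0.1126	1.4332	1.7726	-0.2379	0.7531	-0.5237	1.1557	-1.9915	1.2011	-2.0671	0.3325	-1.809	-0.4119	0.9593	1.3573	-0.9294	-0.1603	-1.4655	-0.1044	1.6646	0.7028
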