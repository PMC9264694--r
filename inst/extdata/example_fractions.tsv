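individual	myeloid	purity
s01	0.7649	0.4464
s02	0.6286	0.4995
s03	0.5863	0.4825
s04	0.5274	0.4576
s05	0.5423	0.6382
s06	0.461	0.8799
s07	0.1543	0.4229
s08	0.7036	0.4275
s09	0.4453	0.5009
s10	0.4257	0.4364
s11	0.2454	0.8217
s12	0.1321	0.882
s13	0.3111	0.8716
s14	0.176	0.3529
s15	0.2778	0.5923
s16	0.0677	0.7873
s17	0.3637	0.8702
s18	0.7836	0.6536
s19	0.6199	0.4592
s20	0.8142	0.6556
s21	0.5821	0.6953
s22	0.0499	0.8868
s23	0.3729	0.6952
s24	0.0088	0.7693
s25	0.8925	0.8051
s26	0.7624	0.4831
s27	0.5864	0.3763
s28	0.8773	0.5019
s29	0.8416	0.6963
s30	0.7102	0.4844
s31	0.4378	0.4802
s32	0.285	0.8544
s33	0.1128	0.7248
s34	0.6485	0.4548
s35	0.3126	0.8042
s36	0.5566	0.8947
s37	0.1849	0.6708
s38	0.1779	0.5655
s39	0.123	0.5639
s40	0.9349	0.6144
s41	0.163	0.5215
s42	0.7884	0.6687
s43	0.0926	0.7602
s44	0.4499	0.3772
s45	0.4209	0.3098
s46	0.9687	0.4066
s47	0.2975	0.8628
s48	0.8251	0.4832
s49	0.242	0.7223
s50	0.8282	0.6794
s51	0.1549	0.3262
s52	0.7012	0.889
s53	0.7812	0.8478
s54	0.2717	0.6178
s55	0.2344	0.8219
s56	0.9622	0.6165
s57	0.7216	0.5505
s58	0.9619	0.3997
s59	0.6771	0.3712
s60	0.9227	0.863
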