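chrom	snp_shared	snp_different	indel_shared	indel_different
Chr01	12245	0	4336	0
Chr02	3255	2	1197	2
Chr03	4313	1	1841	2
Chr04	4082	2	1331	1
Chr05	4645	0	1592	0
Chr06	3141	1	1275	0
Chr07	2112	0	750	1
Chr08	7665	1	2339	0
Chr09	2493	0	979	0
Chr10	2460	0	965	5
Chr11	3772	2	1216	0
Chr12	3504	1	1121	1
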