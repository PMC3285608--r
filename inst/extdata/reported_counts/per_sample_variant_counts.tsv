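chrom	snp_IR24	snp_MH63	snp_SH527	indel_IR24	indel_MH63	indel_SH527	sv_IR24	sv_MH63	sv_SH527
Chr01	36134	34498	33949	8026	7755	7779	528	488	491
Chr02	25139	36400	29835	5258	8064	6868	215	274	246
Chr03	19810	30599	27263	4249	7097	6519	322	363	352
Chr04	19042	26016	22324	3413	4986	4259	273	276	284
Chr05	32928	21990	21396	6212	4726	4638	283	241	232
Chr06	16015	24585	25190	3187	4880	5247	233	261	262
Chr07	12093	13607	10325	2061	2388	1807	98	108	88
Chr08	29097	27334	26804	5564	5501	5491	423	382	390
Chr09	17905	13685	13451	3657	2723	2891	153	115	120
Chr10	21873	16421	14736	4281	3315	3105	269	201	189
Chr11	19377	19470	16873	3472	3625	3329	297	267	252
Chr12	17970	24159	17716	3467	4598	3567	192	250	221
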