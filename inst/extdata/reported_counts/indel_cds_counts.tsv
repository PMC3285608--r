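chrom	noncds_shared_IR24_MH63	cds_shared_IR24_MH63	noncds_different_IR24_MH63	cds_different_IR24_MH63	noncds_shared_IR24_SH527	cds_shared_IR24_SH527	noncds_different_IR24_SH527	cds_different_IR24_SH527	noncds_shared_MH63_SH527	cds_shared_MH63_SH527	noncds_different_MH63_SH527	cds_different_MH63_SH527	noncds_shared_threeway	cds_shared_threeway
Chr01	1159	123	20	1	1212	128	15	1	1288	129	9	1	1033	108
Chr02	433	61	28	0	360	58	18	0	859	73	27	0	278	51
Chr03	524	69	14	0	550	71	8	0	1047	83	13	0	451	61
Chr04	383	63	13	0	499	68	3	0	615	76	12	0	324	55
Chr05	382	52	14	0	404	52	18	0	608	57	2	0	324	42
Chr06	398	48	3	0	381	43	2	0	801	54	5	0	329	37
Chr07	243	42	5	0	233	43	6	0	233	37	2	0	192	34
Chr08	548	56	25	0	554	62	21	0	791	77	3	0	464	49
Chr09	272	34	15	0	383	43	11	0	364	35	9	0	228	29
Chr10	303	41	11	0	371	41	6	0	281	41	16	0	219	34
Chr11	286	36	11	0	462	54	3	0	288	38	10	0	242	30
Chr12	311	41	9	0	358	42	2	0	367	35	19	0	223	29
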