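chrom	snp_shared_IR24_MH63	snp_different_IR24_MH63	snp_shared_IR24_SH527	snp_different_IR24_SH527	snp_shared_MH63_SH527	snp_different_MH63_SH527	indel_shared_IR24_MH63	indel_different_IR24_MH63	indel_shared_IR24_SH527	indel_different_IR24_SH527	indel_shared_MH63_SH527	indel_different_MH63_SH527
Chr01	16776	364	17425	437	20167	191	5107	86	5380	70	5761	26
Chr02	6207	331	5548	470	13209	586	1833	162	1717	97	3747	170
Chr03	6268	216	6708	275	15437	333	2191	66	2410	51	4699	54
Chr04	5813	257	7138	618	11451	275	1597	49	2184	19	2732	41
Chr05	7075	239	7400	208	10666	121	2056	73	2058	88	3045	28
Chr06	5042	211	4631	229	13302	150	1663	17	1518	22	3541	23
Chr07	3697	92	3412	181	3964	169	1063	22	1017	15	979	17
Chr08	10698	271	10938	335	16565	109	2745	132	2847	117	4227	14
Chr09	3961	164	5089	398	6062	261	1218	56	1693	49	1655	32
Chr10	4809	234	5513	275	5085	152	1514	57	1808	50	1381	56
Chr11	5407	194	9257	150	6440	163	1430	71	2406	22	1594	58
Chr12	6203	226	6530	422	7016	417	1636	69	1898	34	1705	94
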