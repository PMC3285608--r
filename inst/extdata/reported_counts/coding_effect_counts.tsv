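chrom	syn_shared_IR24_MH63	nonsyn_shared_IR24_MH63	syn_different_IR24_MH63	nonsyn_different_IR24_MH63	syn_shared_IR24_SH527	nonsyn_shared_IR24_SH527	syn_different_IR24_SH527	nonsyn_different_IR24_SH527	syn_shared_MH63_SH527	nonsyn_shared_MH63_SH527	syn_different_MH63_SH527	nonsyn_different_MH63_SH527	syn_shared_threeway	nonsyn_shared_threeway
Chr01	454	559	5	11	475	592	15	8	561	699	1	4	343	419
Chr02	237	223	9	12	229	206	13	8	504	560	22	18	141	127
Chr03	144	221	3	6	172	246	3	10	327	513	5	7	106	170
Chr04	119	182	6	16	163	221	17	25	286	421	6	16	88	113
Chr05	168	220	4	10	206	251	0	16	250	322	4	5	127	154
Chr06	192	229	4	3	151	225	3	5	383	486	1	5	118	161
Chr07	118	158	0	3	94	139	4	7	97	161	4	5	61	92
Chr08	275	355	7	8	279	362	8	7	404	599	2	1	190	247
Chr09	99	149	1	4	143	195	12	23	150	212	4	12	71	104
Chr10	118	173	6	14	135	228	8	14	127	202	6	5	62	112
Chr11	188	243	1	6	291	419	0	4	221	290	5	8	138	168
Chr12	178	250	8	6	184	282	11	11	207	273	16	11	111	158
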