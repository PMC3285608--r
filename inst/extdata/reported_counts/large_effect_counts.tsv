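chrom	atg_IR24_MH63	premature_IR24_MH63	stop_IR24_MH63	atg_IR24_SH527	premature_IR24_SH527	stop_IR24_SH527	atg_MH63_SH527	premature_MH63_SH527	stop_MH63_SH527	atg_threeway	premature_threeway	stop_threeway
Chr01	0	8	3	0	8	4	0	12	4	0	7	2
Chr02	4	3	3	1	2	1	0	4	3	0	0	1
Chr03	1	5	2	1	7	2	0	13	4	0	4	2
Chr04	0	4	3	1	6	3	0	8	3	0	3	2
Chr05	0	7	1	0	9	1	0	5	4	0	5	1
Chr06	0	2	0	0	3	0	0	5	0	0	1	0
Chr07	0	1	0	0	0	0	0	2	0	0	0	0
Chr08	0	6	2	0	9	2	0	14	2	0	5	2
Chr09	0	5	1	0	7	1	0	6	2	0	3	1
Chr10	0	6	3	0	7	1	1	5	3	0	3	1
Chr11	0	2	2	0	6	3	0	2	2	0	0	1
Chr12	0	1	1	0	5	0	0	6	0	0	1	0
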