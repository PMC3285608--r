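table	key	total
per_sample_variant	snp_IR24	267383
per_sample_variant	snp_MH63	288764
per_sample_variant	snp_SH527	259862
per_sample_variant	indel_IR24	52847
per_sample_variant	indel_MH63	59658
per_sample_variant	indel_SH527	55500
per_sample_variant	sv_IR24	3286
per_sample_variant	sv_MH63	3226
per_sample_variant	sv_SH527	3127
pairwise_comparison	snp_shared_IR24_MH63	81956
pairwise_comparison	snp_different_IR24_MH63	2799
pairwise_comparison	snp_shared_IR24_SH527	89589
pairwise_comparison	snp_different_IR24_SH527	3998
pairwise_comparison	snp_shared_MH63_SH527	129364
pairwise_comparison	snp_different_MH63_SH527	2927
pairwise_comparison	indel_shared_IR24_MH63	24053
pairwise_comparison	indel_different_IR24_MH63	860
pairwise_comparison	indel_shared_IR24_SH527	26936
pairwise_comparison	indel_different_IR24_SH527	634
pairwise_comparison	indel_shared_MH63_SH527	35066
pairwise_comparison	indel_different_MH63_SH527	613
threeway_comparison	snp_shared	53687
threeway_comparison	snp_different	10
threeway_comparison	indel_shared	18942
threeway_comparison	indel_different	12
coding_effect	syn_shared_IR24_MH63	2290
coding_effect	nonsyn_shared_IR24_MH63	2962
coding_effect	syn_different_IR24_MH63	54
coding_effect	nonsyn_different_IR24_MH63	99
coding_effect	syn_shared_IR24_SH527	2522
coding_effect	nonsyn_shared_IR24_SH527	3366
coding_effect	syn_different_IR24_SH527	94
coding_effect	nonsyn_different_IR24_SH527	138
coding_effect	syn_shared_MH63_SH527	3517
coding_effect	nonsyn_shared_MH63_SH527	4738
coding_effect	syn_different_MH63_SH527	76
coding_effect	nonsyn_different_MH63_SH527	97
coding_effect	syn_shared_threeway	1556
coding_effect	nonsyn_shared_threeway	2025
indel_cds	noncds_shared_IR24_MH63	5242
indel_cds	cds_shared_IR24_MH63	666
indel_cds	noncds_different_IR24_MH63	168
indel_cds	cds_different_IR24_MH63	1
indel_cds	noncds_shared_IR24_SH527	5767
indel_cds	cds_shared_IR24_SH527	705
indel_cds	noncds_different_IR24_SH527	113
indel_cds	cds_different_IR24_SH527	1
indel_cds	noncds_shared_MH63_SH527	7542
indel_cds	cds_shared_MH63_SH527	735
indel_cds	noncds_different_MH63_SH527	127
indel_cds	cds_different_MH63_SH527	1
indel_cds	noncds_shared_threeway	4307
indel_cds	cds_shared_threeway	559
large_effect	atg_IR24_MH63	5
large_effect	premature_IR24_MH63	50
large_effect	stop_IR24_MH63	21
large_effect	atg_IR24_SH527	3
large_effect	premature_IR24_SH527	69
large_effect	stop_IR24_SH527	18
large_effect	atg_MH63_SH527	1
large_effect	premature_MH63_SH527	82
large_effect	stop_MH63_SH527	27
large_effect	atg_threeway	0
large_effect	premature_threeway	32
large_effect	stop_threeway	13
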