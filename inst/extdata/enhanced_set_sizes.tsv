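# published enhanced-gene-set sizes and pairwise overlaps for the four
# appendage libraries (FA/MA = female/male antennae, FP/MP = female/male
# maxillary palps); shared = genes enhanced in both sets of the pair
comparison	set_a	size_a	set_b	size_b	shared
female_antennae_vs_female_palps	FP	1906	FA	2277	1158
male_antennae_vs_male_palps	MP	2284	MA	3037	1208
female_palps_vs_male_palps	FP	1906	MP	2284	778
female_antennae_vs_male_antennae	FA	2277	MA	3037	1381
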