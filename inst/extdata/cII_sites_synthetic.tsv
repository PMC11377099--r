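gene	site	sequence	methylated_positions	adducted	hotspot	replicate	dataset_tag	series_prefix
cII	hs1	AGCTTCGATCCAGGTGGCGGCTCCC	6	1	1	1	cII	cII_hs1_adduct_rep1
cII	hs1	AGCTTCGATCCAGGTGGCGGCTCCC	6	1	1	2	cII	cII_hs1_adduct_rep2
cII	hs1	AGCTTCGATCCAGGTGGCGGCTCCC	6	1	1	3	cII	cII_hs1_adduct_rep3
cII	hs1	AGCTTCGATCCAGGTGGCGGCTCCC	6	0	1	1	cII	cII_hs1_control_rep1
cII	hs1	AGCTTCGATCCAGGTGGCGGCTCCC	6	0	1	2	cII	cII_hs1_control_rep2
cII	hs1	AGCTTCGATCCAGGTGGCGGCTCCC	6	0	1	3	cII	cII_hs1_control_rep3
cII	hs2	TCATGCGAACTGATCCACCCCCGGC	6	1	1	1	cII	cII_hs2_adduct_rep1
cII	hs2	TCATGCGAACTGATCCACCCCCGGC	6	1	1	2	cII	cII_hs2_adduct_rep2
cII	hs2	TCATGCGAACTGATCCACCCCCGGC	6	1	1	3	cII	cII_hs2_adduct_rep3
cII	hs2	TCATGCGAACTGATCCACCCCCGGC	6	0	1	1	cII	cII_hs2_control_rep1
cII	hs2	TCATGCGAACTGATCCACCCCCGGC	6	0	1	2	cII	cII_hs2_control_rep2
cII	hs2	TCATGCGAACTGATCCACCCCCGGC	6	0	1	3	cII	cII_hs2_control_rep3
cII	hs3	CATGGCGACACTCAGCACGGCGGAT	6	1	1	1	cII	cII_hs3_adduct_rep1
cII	hs3	CATGGCGACACTCAGCACGGCGGAT	6	1	1	2	cII	cII_hs3_adduct_rep2
cII	hs3	CATGGCGACACTCAGCACGGCGGAT	6	1	1	3	cII	cII_hs3_adduct_rep3
cII	hs3	CATGGCGACACTCAGCACGGCGGAT	6	0	1	1	cII	cII_hs3_control_rep1
cII	hs3	CATGGCGACACTCAGCACGGCGGAT	6	0	1	2	cII	cII_hs3_control_rep2
cII	hs3	CATGGCGACACTCAGCACGGCGGAT	6	0	1	3	cII	cII_hs3_control_rep3
cII	hs4	TTGCACGAAGTGTACAGACTGGACG	6	1	1	1	cII	cII_hs4_adduct_rep1
cII	hs4	TTGCACGAAGTGTACAGACTGGACG	6	1	1	2	cII	cII_hs4_adduct_rep2
cII	hs4	TTGCACGAAGTGTACAGACTGGACG	6	1	1	3	cII	cII_hs4_adduct_rep3
cII	hs4	TTGCACGAAGTGTACAGACTGGACG	6	0	1	1	cII	cII_hs4_control_rep1
cII	hs4	TTGCACGAAGTGTACAGACTGGACG	6	0	1	2	cII	cII_hs4_control_rep2
cII	hs4	TTGCACGAAGTGTACAGACTGGACG	6	0	1	3	cII	cII_hs4_control_rep3
cII	hs5	GCTAACGTGCACAGAATTCGTGTAT	6	1	1	1	cII	cII_hs5_adduct_rep1
cII	hs5	GCTAACGTGCACAGAATTCGTGTAT	6	1	1	2	cII	cII_hs5_adduct_rep2
cII	hs5	GCTAACGTGCACAGAATTCGTGTAT	6	1	1	3	cII	cII_hs5_adduct_rep3
cII	hs5	GCTAACGTGCACAGAATTCGTGTAT	6	0	1	1	cII	cII_hs5_control_rep1
cII	hs5	GCTAACGTGCACAGAATTCGTGTAT	6	0	1	2	cII	cII_hs5_control_rep2
cII	hs5	GCTAACGTGCACAGAATTCGTGTAT	6	0	1	3	cII	cII_hs5_control_rep3
cII	nh1	GTGGTCGTTGTGCTCCCCCCATACT	6	1	0	1	cII	cII_nh1_adduct_rep1
cII	nh1	GTGGTCGTTGTGCTCCCCCCATACT	6	1	0	2	cII	cII_nh1_adduct_rep2
cII	nh1	GTGGTCGTTGTGCTCCCCCCATACT	6	1	0	3	cII	cII_nh1_adduct_rep3
cII	nh1	GTGGTCGTTGTGCTCCCCCCATACT	6	0	0	1	cII	cII_nh1_control_rep1
cII	nh1	GTGGTCGTTGTGCTCCCCCCATACT	6	0	0	2	cII	cII_nh1_control_rep2
cII	nh1	GTGGTCGTTGTGCTCCCCCCATACT	6	0	0	3	cII	cII_nh1_control_rep3
cII	nh2	TTGTCCGAACAGAAAGGCCTGTGCG	6	1	0	1	cII	cII_nh2_adduct_rep1
cII	nh2	TTGTCCGAACAGAAAGGCCTGTGCG	6	1	0	2	cII	cII_nh2_adduct_rep2
cII	nh2	TTGTCCGAACAGAAAGGCCTGTGCG	6	1	0	3	cII	cII_nh2_adduct_rep3
cII	nh2	TTGTCCGAACAGAAAGGCCTGTGCG	6	0	0	1	cII	cII_nh2_control_rep1
cII	nh2	TTGTCCGAACAGAAAGGCCTGTGCG	6	0	0	2	cII	cII_nh2_control_rep2
cII	nh2	TTGTCCGAACAGAAAGGCCTGTGCG	6	0	0	3	cII	cII_nh2_control_rep3
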