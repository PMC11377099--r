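gene	site	sequence	methylated_positions	adducted	hotspot	replicate	dataset_tag	series_prefix
lacZ	hs1	CCCCCCGCTACCCTCGCGCCCGACC	6	1	1	1	lacZ	lacZ_hs1_adduct_rep1
lacZ	hs1	CCCCCCGCTACCCTCGCGCCCGACC	6	1	1	2	lacZ	lacZ_hs1_adduct_rep2
lacZ	hs1	CCCCCCGCTACCCTCGCGCCCGACC	6	1	1	3	lacZ	lacZ_hs1_adduct_rep3
lacZ	hs1	CCCCCCGCTACCCTCGCGCCCGACC	6	0	1	1	lacZ	lacZ_hs1_control_rep1
lacZ	hs1	CCCCCCGCTACCCTCGCGCCCGACC	6	0	1	2	lacZ	lacZ_hs1_control_rep2
lacZ	hs1	CCCCCCGCTACCCTCGCGCCCGACC	6	0	1	3	lacZ	lacZ_hs1_control_rep3
lacZ	hs2	CGCCACGGTCCGTCCGCCATAGCCG	6	1	1	1	lacZ	lacZ_hs2_adduct_rep1
lacZ	hs2	CGCCACGGTCCGTCCGCCATAGCCG	6	1	1	2	lacZ	lacZ_hs2_adduct_rep2
lacZ	hs2	CGCCACGGTCCGTCCGCCATAGCCG	6	1	1	3	lacZ	lacZ_hs2_adduct_rep3
lacZ	hs2	CGCCACGGTCCGTCCGCCATAGCCG	6	0	1	1	lacZ	lacZ_hs2_control_rep1
lacZ	hs2	CGCCACGGTCCGTCCGCCATAGCCG	6	0	1	2	lacZ	lacZ_hs2_control_rep2
lacZ	hs2	CGCCACGGTCCGTCCGCCATAGCCG	6	0	1	3	lacZ	lacZ_hs2_control_rep3
lacZ	hs3	GCATCCGCCCCGCTCGGGTCGAGCC	6	1	1	1	lacZ	lacZ_hs3_adduct_rep1
lacZ	hs3	GCATCCGCCCCGCTCGGGTCGAGCC	6	1	1	2	lacZ	lacZ_hs3_adduct_rep2
lacZ	hs3	GCATCCGCCCCGCTCGGGTCGAGCC	6	1	1	3	lacZ	lacZ_hs3_adduct_rep3
lacZ	hs3	GCATCCGCCCCGCTCGGGTCGAGCC	6	0	1	1	lacZ	lacZ_hs3_control_rep1
lacZ	hs3	GCATCCGCCCCGCTCGGGTCGAGCC	6	0	1	2	lacZ	lacZ_hs3_control_rep2
lacZ	hs3	GCATCCGCCCCGCTCGGGTCGAGCC	6	0	1	3	lacZ	lacZ_hs3_control_rep3
lacZ	hs4	CCTCGCGACCCCGACCGGAGGCCGG	6	1	1	1	lacZ	lacZ_hs4_adduct_rep1
lacZ	hs4	CCTCGCGACCCCGACCGGAGGCCGG	6	1	1	2	lacZ	lacZ_hs4_adduct_rep2
lacZ	hs4	CCTCGCGACCCCGACCGGAGGCCGG	6	1	1	3	lacZ	lacZ_hs4_adduct_rep3
lacZ	hs4	CCTCGCGACCCCGACCGGAGGCCGG	6	0	1	1	lacZ	lacZ_hs4_control_rep1
lacZ	hs4	CCTCGCGACCCCGACCGGAGGCCGG	6	0	1	2	lacZ	lacZ_hs4_control_rep2
lacZ	hs4	CCTCGCGACCCCGACCGGAGGCCGG	6	0	1	3	lacZ	lacZ_hs4_control_rep3
lacZ	hs5	CGGCGCGCAAGCGGGGACCCGGGCC	6	1	1	1	lacZ	lacZ_hs5_adduct_rep1
lacZ	hs5	CGGCGCGCAAGCGGGGACCCGGGCC	6	1	1	2	lacZ	lacZ_hs5_adduct_rep2
lacZ	hs5	CGGCGCGCAAGCGGGGACCCGGGCC	6	1	1	3	lacZ	lacZ_hs5_adduct_rep3
lacZ	hs5	CGGCGCGCAAGCGGGGACCCGGGCC	6	0	1	1	lacZ	lacZ_hs5_control_rep1
lacZ	hs5	CGGCGCGCAAGCGGGGACCCGGGCC	6	0	1	2	lacZ	lacZ_hs5_control_rep2
lacZ	hs5	CGGCGCGCAAGCGGGGACCCGGGCC	6	0	1	3	lacZ	lacZ_hs5_control_rep3
lacZ	nh1	TATTTCGTCAAATTTAGTAAGCATA	6	1	0	1	lacZ	lacZ_nh1_adduct_rep1
lacZ	nh1	TATTTCGTCAAATTTAGTAAGCATA	6	1	0	2	lacZ	lacZ_nh1_adduct_rep2
lacZ	nh1	TATTTCGTCAAATTTAGTAAGCATA	6	1	0	3	lacZ	lacZ_nh1_adduct_rep3
lacZ	nh1	TATTTCGTCAAATTTAGTAAGCATA	6	0	0	1	lacZ	lacZ_nh1_control_rep1
lacZ	nh1	TATTTCGTCAAATTTAGTAAGCATA	6	0	0	2	lacZ	lacZ_nh1_control_rep2
lacZ	nh1	TATTTCGTCAAATTTAGTAAGCATA	6	0	0	3	lacZ	lacZ_nh1_control_rep3
lacZ	nh2	CAAAACGAACATATCAGACTGCGTA	6	1	0	1	lacZ	lacZ_nh2_adduct_rep1
lacZ	nh2	CAAAACGAACATATCAGACTGCGTA	6	1	0	2	lacZ	lacZ_nh2_adduct_rep2
lacZ	nh2	CAAAACGAACATATCAGACTGCGTA	6	1	0	3	lacZ	lacZ_nh2_adduct_rep3
lacZ	nh2	CAAAACGAACATATCAGACTGCGTA	6	0	0	1	lacZ	lacZ_nh2_control_rep1
lacZ	nh2	CAAAACGAACATATCAGACTGCGTA	6	0	0	2	lacZ	lacZ_nh2_control_rep2
lacZ	nh2	CAAAACGAACATATCAGACTGCGTA	6	0	0	3	lacZ	lacZ_nh2_control_rep3
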