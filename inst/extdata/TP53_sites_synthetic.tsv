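gene	site	sequence	methylated_positions	adducted	hotspot	replicate	dataset_tag	series_prefix
TP53	157	CGGGACGTCCCTGCGACCCACCTGC	6	1	1	1	TP53	TP53_157_adduct_rep1
TP53	157	CGGGACGTCCCTGCGACCCACCTGC	6	1	1	2	TP53	TP53_157_adduct_rep2
TP53	157	CGGGACGTCCCTGCGACCCACCTGC	6	1	1	3	TP53	TP53_157_adduct_rep3
TP53	157	CGGGACGTCCCTGCGACCCACCTGC	6	0	1	1	TP53	TP53_157_control_rep1
TP53	157	CGGGACGTCCCTGCGACCCACCTGC	6	0	1	2	TP53	TP53_157_control_rep2
TP53	157	CGGGACGTCCCTGCGACCCACCTGC	6	0	1	3	TP53	TP53_157_control_rep3
TP53	158	GTCCACGGGTGCACGGGTGGCGGGG	6	1	1	1	TP53	TP53_158_adduct_rep1
TP53	158	GTCCACGGGTGCACGGGTGGCGGGG	6	1	1	2	TP53	TP53_158_adduct_rep2
TP53	158	GTCCACGGGTGCACGGGTGGCGGGG	6	1	1	3	TP53	TP53_158_adduct_rep3
TP53	158	GTCCACGGGTGCACGGGTGGCGGGG	6	0	1	1	TP53	TP53_158_control_rep1
TP53	158	GTCCACGGGTGCACGGGTGGCGGGG	6	0	1	2	TP53	TP53_158_control_rep2
TP53	158	GTCCACGGGTGCACGGGTGGCGGGG	6	0	1	3	TP53	TP53_158_control_rep3
TP53	245	ACCGGCGTTACCGGGTGCTCGGGCC	6	1	1	1	TP53	TP53_245_adduct_rep1
TP53	245	ACCGGCGTTACCGGGTGCTCGGGCC	6	1	1	2	TP53	TP53_245_adduct_rep2
TP53	245	ACCGGCGTTACCGGGTGCTCGGGCC	6	1	1	3	TP53	TP53_245_adduct_rep3
TP53	245	ACCGGCGTTACCGGGTGCTCGGGCC	6	0	1	1	TP53	TP53_245_control_rep1
TP53	245	ACCGGCGTTACCGGGTGCTCGGGCC	6	0	1	2	TP53	TP53_245_control_rep2
TP53	245	ACCGGCGTTACCGGGTGCTCGGGCC	6	0	1	3	TP53	TP53_245_control_rep3
TP53	248	TACGGCGAGGGTAGTGACCAGCACG	6	1	1	1	TP53	TP53_248_adduct_rep1
TP53	248	TACGGCGAGGGTAGTGACCAGCACG	6	1	1	2	TP53	TP53_248_adduct_rep2
TP53	248	TACGGCGAGGGTAGTGACCAGCACG	6	1	1	3	TP53	TP53_248_adduct_rep3
TP53	248	TACGGCGAGGGTAGTGACCAGCACG	6	0	1	1	TP53	TP53_248_control_rep1
TP53	248	TACGGCGAGGGTAGTGACCAGCACG	6	0	1	2	TP53	TP53_248_control_rep2
TP53	248	TACGGCGAGGGTAGTGACCAGCACG	6	0	1	3	TP53	TP53_248_control_rep3
TP53	273	TAGTCCGTCGCCTCCCCGAGCCAAA	6	1	1	1	TP53	TP53_273_adduct_rep1
TP53	273	TAGTCCGTCGCCTCCCCGAGCCAAA	6	1	1	2	TP53	TP53_273_adduct_rep2
TP53	273	TAGTCCGTCGCCTCCCCGAGCCAAA	6	1	1	3	TP53	TP53_273_adduct_rep3
TP53	273	TAGTCCGTCGCCTCCCCGAGCCAAA	6	0	1	1	TP53	TP53_273_control_rep1
TP53	273	TAGTCCGTCGCCTCCCCGAGCCAAA	6	0	1	2	TP53	TP53_273_control_rep2
TP53	273	TAGTCCGTCGCCTCCCCGAGCCAAA	6	0	1	3	TP53	TP53_273_control_rep3
TP53	282	CCCTGCGGTGTGGTGTCCCGGTCGG	6	1	1	1	TP53	TP53_282_adduct_rep1
TP53	282	CCCTGCGGTGTGGTGTCCCGGTCGG	6	1	1	2	TP53	TP53_282_adduct_rep2
TP53	282	CCCTGCGGTGTGGTGTCCCGGTCGG	6	1	1	3	TP53	TP53_282_adduct_rep3
TP53	282	CCCTGCGGTGTGGTGTCCCGGTCGG	6	0	1	1	TP53	TP53_282_control_rep1
TP53	282	CCCTGCGGTGTGGTGTCCCGGTCGG	6	0	1	2	TP53	TP53_282_control_rep2
TP53	282	CCCTGCGGTGTGGTGTCCCGGTCGG	6	0	1	3	TP53	TP53_282_control_rep3
TP53	170	TTAGTCGAGAATCAAATAATCTATT	6	1	0	1	TP53	TP53_170_adduct_rep1
TP53	170	TTAGTCGAGAATCAAATAATCTATT	6	1	0	2	TP53	TP53_170_adduct_rep2
TP53	170	TTAGTCGAGAATCAAATAATCTATT	6	1	0	3	TP53	TP53_170_adduct_rep3
TP53	170	TTAGTCGAGAATCAAATAATCTATT	6	0	0	1	TP53	TP53_170_control_rep1
TP53	170	TTAGTCGAGAATCAAATAATCTATT	6	0	0	2	TP53	TP53_170_control_rep2
TP53	170	TTAGTCGAGAATCAAATAATCTATT	6	0	0	3	TP53	TP53_170_control_rep3
TP53	186	AATTGCGGTATTCCTACCACTGCGG	6	1	0	1	TP53	TP53_186_adduct_rep1
TP53	186	AATTGCGGTATTCCTACCACTGCGG	6	1	0	2	TP53	TP53_186_adduct_rep2
TP53	186	AATTGCGGTATTCCTACCACTGCGG	6	1	0	3	TP53	TP53_186_adduct_rep3
TP53	186	AATTGCGGTATTCCTACCACTGCGG	6	0	0	1	TP53	TP53_186_control_rep1
TP53	186	AATTGCGGTATTCCTACCACTGCGG	6	0	0	2	TP53	TP53_186_control_rep2
TP53	186	AATTGCGGTATTCCTACCACTGCGG	6	0	0	3	TP53	TP53_186_control_rep3
TP53	202	CTTAACGTGACACCGGAACTCCTTT	6	1	0	1	TP53	TP53_202_adduct_rep1
TP53	202	CTTAACGTGACACCGGAACTCCTTT	6	1	0	2	TP53	TP53_202_adduct_rep2
TP53	202	CTTAACGTGACACCGGAACTCCTTT	6	1	0	3	TP53	TP53_202_adduct_rep3
TP53	202	CTTAACGTGACACCGGAACTCCTTT	6	0	0	1	TP53	TP53_202_control_rep1
TP53	202	CTTAACGTGACACCGGAACTCCTTT	6	0	0	2	TP53	TP53_202_control_rep2
TP53	202	CTTAACGTGACACCGGAACTCCTTT	6	0	0	3	TP53	TP53_202_control_rep3
TP53	213	GTACACGAAGATATAACGTATCGCA	6	1	0	1	TP53	TP53_213_adduct_rep1
TP53	213	GTACACGAAGATATAACGTATCGCA	6	1	0	2	TP53	TP53_213_adduct_rep2
TP53	213	GTACACGAAGATATAACGTATCGCA	6	1	0	3	TP53	TP53_213_adduct_rep3
TP53	213	GTACACGAAGATATAACGTATCGCA	6	0	0	1	TP53	TP53_213_control_rep1
TP53	213	GTACACGAAGATATAACGTATCGCA	6	0	0	2	TP53	TP53_213_control_rep2
TP53	213	GTACACGAAGATATAACGTATCGCA	6	0	0	3	TP53	TP53_213_control_rep3
TP53	267	ATCTGCGATTTATTTTGCTTTATCG	6	1	0	1	TP53	TP53_267_adduct_rep1
TP53	267	ATCTGCGATTTATTTTGCTTTATCG	6	1	0	2	TP53	TP53_267_adduct_rep2
TP53	267	ATCTGCGATTTATTTTGCTTTATCG	6	1	0	3	TP53	TP53_267_adduct_rep3
TP53	267	ATCTGCGATTTATTTTGCTTTATCG	6	0	0	1	TP53	TP53_267_control_rep1
TP53	267	ATCTGCGATTTATTTTGCTTTATCG	6	0	0	2	TP53	TP53_267_control_rep2
TP53	267	ATCTGCGATTTATTTTGCTTTATCG	6	0	0	3	TP53	TP53_267_control_rep3
TP53	290	TTATTCGACTTCCTACATTAGGCCC	6	1	0	1	TP53	TP53_290_adduct_rep1
TP53	290	TTATTCGACTTCCTACATTAGGCCC	6	1	0	2	TP53	TP53_290_adduct_rep2
TP53	290	TTATTCGACTTCCTACATTAGGCCC	6	1	0	3	TP53	TP53_290_adduct_rep3
TP53	290	TTATTCGACTTCCTACATTAGGCCC	6	0	0	1	TP53	TP53_290_control_rep1
TP53	290	TTATTCGACTTCCTACATTAGGCCC	6	0	0	2	TP53	TP53_290_control_rep2
TP53	290	TTATTCGACTTCCTACATTAGGCCC	6	0	0	3	TP53	TP53_290_control_rep3
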