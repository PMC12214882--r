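class	channel	feature	map_version
SBS96	A[C>T]G	n_ct_g	0.1.0
SBS96	C[C>T]G	n_ct_g	0.1.0
SBS96	G[C>T]G	n_ct_g	0.1.0
SBS96	T[C>T]G	n_ct_g	0.1.0
SBS96	A[C>G]T	n_cg_t	0.1.0
SBS96	C[C>G]T	n_cg_t	0.1.0
SBS96	G[C>G]T	n_cg_t	0.1.0
SBS96	T[C>G]T	n_cg_t	0.1.0
ID83	5:Del:M:1	del5_mh	0.1.0
ID83	5:Del:M:2	del5_mh	0.1.0
ID83	5:Del:M:3	del5_mh	0.1.0
ID83	5:Del:M:4	del5_mh	0.1.0
ID83	5:Del:M:5	del5_mh	0.1.0
CN48	1:LOH:1-10Mb	loh_1_40	0.1.0
CN48	1:LOH:10-40Mb	loh_1_40	0.1.0
CN48	2:LOH:1-10Mb	loh_1_40	0.1.0
CN48	2:LOH:10-40Mb	loh_1_40	0.1.0
CN48	3-4:LOH:1-10Mb	loh_1_40	0.1.0
CN48	3-4:LOH:10-40Mb	loh_1_40	0.1.0
CN48	5-8:LOH:1-10Mb	loh_1_40	0.1.0
CN48	5-8:LOH:10-40Mb	loh_1_40	0.1.0
CN48	9+:LOH:1-10Mb	loh_1_40	0.1.0
CN48	9+:LOH:10-40Mb	loh_1_40	0.1.0
CN48	3-4:HET:10-40Mb	het3_9_10_40	0.1.0
CN48	5-8:HET:10-40Mb	het3_9_10_40	0.1.0
CN48	9+:HET:10-40Mb	het3_9_10_40	0.1.0
CN48	2:HET:>40Mb	het2_4_gt40	0.1.0
CN48	3-4:HET:>40Mb	het2_4_gt40	0.1.0
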