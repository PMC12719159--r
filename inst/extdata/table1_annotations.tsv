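variant_id	consequence	cadd	effect_allele	eur_af	splice_flag	eqtl_gene_ids
rs719316	intron_variant	5.92	T	0.529	FALSE	.
rs17603856	intron_variant	10.94	G	0.346	FALSE	.
rs6459480	intron_variant	1.82	A	0.509	FALSE	ENSG00000124788
rs9297016	intron_variant	2.57	G	0.576	FALSE	.
rs7772172	intron_variant	5.02	G	0.576	FALSE	.
rs909788	intron_variant	5.75	C	0.545	FALSE	ENSG00000124788
rs6459472	intron_variant	2.97	G	0.573	FALSE	.
rs6915310	intron_variant	4.27	T	0.182	FALSE	.
rs9367926	intron_variant	6.59	G	0.18	FALSE	.
rs2237199	intron_variant	3.49	A	0.112	FALSE	.
rs73366713	intron_variant	2.84	A	0.131	FALSE	.
rs7770062	intron_variant	2.33	A	0.131	FALSE	.
rs3819405	intron_variant	12.1	T	0.34	FALSE	.
rs653178	intron_variant	1.59	T	0.534	FALSE	.
rs848130	intron_variant	2.02	A	0.192	FALSE	.
rs832190	intron_variant	0.58	T	0.603	FALSE	.
rs3821902	intron_variant	0.81	G	0.15	FALSE	.
rs13434089	intron_variant	4.59	C	0.141	FALSE	.
rs5021328	intron_variant	0.63	C	0.644	FALSE	.
rs16003	intron_variant	8.26	T	0.463	FALSE	.
rs363096	splice_region_variant	6.29	C	0.591	TRUE	.
rs7685686	intron_variant	6.39	G	0.433	FALSE	.
rs82334	intron_variant	4.13	C	0.323	FALSE	.
rs61348208	intron_variant	5.46	T	0.389	FALSE	.
rs2071703	intron_variant	2.52	C	0.325	FALSE	.
rs113928896	intron_variant	0.32	T	0.143	FALSE	.
rs362307	3_prime_UTR_variant	3.23	T	0.063	FALSE	.
rs6828882	intron_variant	8.54	G	0.101	FALSE	.
rs2798297	intron_variant	2.08	A	0.353	FALSE	.
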