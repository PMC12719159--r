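gene_symbol	gene_id	trait_label	trait_category	study_id	pubmed_id	source	l2g	variant_id	chrom	pos	gwas_p	effect	effect_ci_low	effect_ci_high	effect_type	ancestries
ATXN1	ENSG00000124788	multiple sclerosis	disease	IMSGC_2011	PM100011	GWAS_catalog	0.79	rs719316	6	16310000	2e-13	1.07	1.05	1.09	odds_ratio	EUR
ATXN1	ENSG00000124788	systemic lupus erythematosus	disease	Morris_2016	PM100021	GWAS_catalog	0.79	rs17603856	6	16320000	3e-12	0.88	0.85	0.91	odds_ratio	EUR
ATXN1	ENSG00000124788	cognitive ability, years of educational attainment or schizophrenia	measurement	Lam_2017	PM100015	GWAS_catalog	0.69	rs6459480	6	16330100	2e-10	.	.	.	.	EUR
ATXN1	ENSG00000124788	household income	measurement	Hill_2016	PM100008	GWAS_catalog	0.7	rs6459480	6	16330100	5e-10	-0.01	-0.02	0.01	beta	EUR
ATXN1	ENSG00000124788	educational attainment	measurement	Lee_2018	PM100017	GWAS_catalog	0.68	rs9297016	6	16330200	1e-9	-0.01	-0.01	0.006	beta	EUR
ATXN1	ENSG00000124788	educational attainment: years of education	measurement	Okbay_2016	PM100023	GWAS_catalog	0.68	rs7772172	6	16330300	1e-8	-0.01	-0.02	0.01	beta	EUR
ATXN1	ENSG00000124788	educational attainment (years of education)	measurement	Lee_2018	PM100017	GWAS_catalog	0.77	rs909788	6	16330000	4e-8	-0.01	-0.011	0.005	beta	EUR
ATXN1	ENSG00000124788	central corneal thickness	measurement	Choquet_2020	PM100004	GWAS_catalog	0.72	rs6459472	6	16340000	3e-9	.	.	.	.	EUR
ATXN1	ENSG00000124788	male-pattern baldness	measurement	Yap_2018	PM100032	GWAS_catalog	0.72	rs6915310	6	16350100	5e-20	0.04	0.03	0.05	beta	EUR
ATXN1	ENSG00000124788	balding type 1	measurement	Kichaev_2019	PM100014	GWAS_catalog	0.71	rs9367926	6	16350000	6e-12	.	.	.	.	EUR
ATXN1	ENSG00000124788	subcutaneous adipose tissue attenuation	measurement	Chu_2021	PM100005	GWAS_catalog	0.57	rs2237199	6	16360000	1e-8	5.67	3.73	7.61	beta	EUR
ATXN1	ENSG00000124788	atrial fibrillation	disease	Nielsen_2018	PM100022	GWAS_catalog	0.55	rs73366713	6	16370100	1.53e-25	0.9	0.88	0.92	odds_ratio	EUR
ATXN1	ENSG00000124788	atrial fibrillation	disease	Roselli_2018	PM100027	GWAS_catalog	0.54	rs7770062	6	16370000	9e-21	0.9	0.88	0.92	odds_ratio	EUR
ATXN1	ENSG00000124788	breast cancer	disease	Michailidou_2017	PM100020	GWAS_catalog	0.53	rs3819405	6	16380000	1.65e-8	0.96	0.95	0.97	odds_ratio	EUR
ATXN2	ENSG00000204842	celiac disease	disease	Dubois_2010	PM100007	GWAS_catalog	0.51	rs653178	12	111460000	6e-14	0.83	0.78	0.87	odds_ratio	EUR
ATXN2	ENSG00000204842	type 1 diabetes	disease	Chiou_2021	PM100003	GWAS_catalog	0.67	rs848130	12	111470000	1.6e-14	0.85	0.82	0.89	odds_ratio	EUR
ATXN7	ENSG00000163635	schizophrenia	disease	Lam_2019	PM100016	GWAS_catalog	0.51	rs832190	3	63870000	4e-8	.	.	.	.	EUR
ATXN7	ENSG00000163635	breast cancer	disease	Michailidou_2017	PM100020	GWAS_catalog	0.54	rs3821902	3	63880000	2.99e-12	1.06	1.05	1.08	odds_ratio	EUR
ATXN7	ENSG00000163635	type 2 diabetes	disease	Vujkovic_2020	PM100031	GWAS_catalog	0.55	rs13434089	3	63890000	4e-31	-0.06	-0.07	0.05	beta	EUR
CACNA1A	ENSG00000141837	appendicular lean mass	measurement	Pei_2020	PM100025	GWAS_catalog	0.86	rs5021328	19	13210000	6.6e-9	-0.01	-0.02	0.01	beta	EUR
CACNA1A	ENSG00000141837	positive affect	measurement	Baselmans_2019	PM100002	GWAS_catalog	0.84	rs16003	19	13220000	3e-8	0.01	0	0.01	beta	EUR
CACNA1A	ENSG00000141837	depressive symptoms	measurement	Baselmans_2019	PM100002	GWAS_catalog	0.84	rs16003	19	13220000	3e-8	0.01	0	0.01	beta	EUR
HTT	ENSG00000197386	noncognitive aspects of educational attainment	measurement	Demange_2021	PM100006	GWAS_catalog	0.72	rs363096	4	3050000	1e-12	0.05	0.04	0.06	beta	EUR
HTT	ENSG00000197386	educational attainment: years of education	measurement	Kichaev_2019	PM100014	GWAS_catalog	0.74	rs363096	4	3050000	1e-10	.	.	.	.	EUR
HTT	ENSG00000197386	depression	disease	Howard_2019	PM100010	GWAS_catalog	0.59	rs7685686	4	3060100	6e-15	0.983	0.979	0.987	odds_ratio	EUR
HTT	ENSG00000197386	frailty index	measurement	Atkins_2021	PM100001	GWAS_catalog	0.54	rs82334	4	3060200	3.1e-10	-0.02	-0.03	0.02	beta	EUR
HTT	ENSG00000197386	parental lifespan	measurement	Timmers_2019	PM100028	GWAS_catalog	0.63	rs61348208	4	3060000	6e-9	0.23	0.15	0.31	beta	EUR
HTT	ENSG00000197386	gastroesophageal reflux disease	disease	Ong_2019	PM100024	GWAS_catalog	0.54	rs7685686	4	3060100	1.1e-8	0.97	0.96	0.98	odds_ratio	EUR
HTT	ENSG00000197386	aging traits: health span, parental lifespan or longevity	measurement	Timmers_2020	PM100029	GWAS_catalog	0.62	rs61348208	4	3060000	3e-8	.	.	.	.	EUR
HTT	ENSG00000197386	vertex-wise sulcal depth	measurement	vanderMeer_2021	PM100033	GWAS_catalog	0.6	rs2071703	4	3060300	3e-8	5.57	3.6	7.54	beta	EUR
HTT	ENSG00000197386	highest math class taken	measurement	Lee_2018	PM100017	GWAS_catalog	0.55	rs113928896	4	3070000	2e-9	0.02	0.01	0.02	beta	EUR
HTT	ENSG00000197386	automobile speeding propensity	measurement	KarlssonLinner_2019	PM100012	GWAS_catalog	0.51	rs362307	4	3080000	6e-14	-0.03	-0.04	0.02	beta	EUR
HTT	ENSG00000197386	worry/vulnerability: special factor of neuroticism	measurement	Hill_2019	PM100009	GWAS_catalog	0.54	rs362307	4	3080000	1e-9	0.01	0.005	0.011	beta	EUR
HTT	ENSG00000197386	walking pace	measurement	Timmins_2020	PM100030	GWAS_catalog	0.54	rs362307	4	3080000	1e-9	-0.01	-0.02	0.01	beta	EUR
HTT	ENSG00000197386	type 2 diabetes	disease	Mahajan_2018	PM100018	GWAS_catalog	0.54	rs362307	4	3080000	1e-9	1.08	1.05	1.11	odds_ratio	EUR
HTT	ENSG00000197386	predicted visceral adipose tissue	measurement	Karlsson_2019	PM100013	GWAS_catalog	0.54	rs362307	4	3080000	2e-9	0.03	0.02	0.04	beta	EUR
HTT	ENSG00000197386	monobrow	measurement	Pickrell_2016	PM100026	GWAS_catalog	0.53	rs6828882	4	3090000	1e-22	.	.	.	.	EUR
HTT	ENSG00000197386	metabolic biomarkers	measurement	Martin_2021	PM100019	GWAS_catalog	0.52	rs2798297	4	3100000	1e-24	.	.	.	.	EUR
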