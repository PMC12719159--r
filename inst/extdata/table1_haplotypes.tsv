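gene_symbol	haplotype_index	tag_variant	member_variants
ATXN1	1	rs719316	rs719316
ATXN1	2	rs17603856	rs17603856
ATXN1	3	rs909788	rs909788;rs6459480;rs9297016;rs7772172
ATXN1	4	rs6459472	rs6459472
ATXN1	5	rs9367926	rs9367926;rs6915310
ATXN1	6	rs2237199	rs2237199
ATXN1	7	rs7770062	rs7770062;rs73366713
ATXN1	8	rs3819405	rs3819405
ATXN2	1	rs653178	rs653178
ATXN2	2	rs848130	rs848130
ATXN7	1	rs832190	rs832190
ATXN7	2	rs3821902	rs3821902
ATXN7	3	rs13434089	rs13434089
CACNA1A	1	rs5021328	rs5021328
CACNA1A	2	rs16003	rs16003
HTT	1	rs363096	rs363096
HTT	2	rs61348208	rs61348208;rs7685686;rs82334;rs2071703
HTT	3	rs113928896	rs113928896
HTT	4	rs362307	rs362307
HTT	5	rs6828882	rs6828882
HTT	6	rs2798297	rs2798297
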