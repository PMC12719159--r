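id_a	id_b	r2
rs363096	rs61348208	0.104735
rs363096	rs7685686	0.139149
rs61348208	rs7685686	0.760449
rs363096	rs82334	0.058143
rs61348208	rs82334	0.843561
rs7685686	rs82334	0.838759
rs363096	rs2071703	0.111609
rs61348208	rs2071703	0.807751
rs7685686	rs2071703	0.83041
rs82334	rs2071703	0.762358
rs363096	rs113928896	0.069353
rs61348208	rs113928896	0.147289
rs7685686	rs113928896	0.115136
rs82334	rs113928896	0.11941
rs2071703	rs113928896	0.127092
rs363096	rs362307	0.093917
rs61348208	rs362307	0.109939
rs7685686	rs362307	0.097083
rs82334	rs362307	0.135783
rs2071703	rs362307	0.087433
rs113928896	rs362307	0.085634
rs363096	rs6828882	0.056923
rs61348208	rs6828882	0.094171
rs7685686	rs6828882	0.148807
rs82334	rs6828882	0.126821
rs2071703	rs6828882	0.065818
rs113928896	rs6828882	0.08769
rs362307	rs6828882	0.144994
rs363096	rs2798297	0.142264
rs61348208	rs2798297	0.093357
rs7685686	rs2798297	0.096189
rs82334	rs2798297	0.140814
rs2071703	rs2798297	0.123293
rs113928896	rs2798297	0.088655
rs362307	rs2798297	0.061921
rs6828882	rs2798297	0.074671
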