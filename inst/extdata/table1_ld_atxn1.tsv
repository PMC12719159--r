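id_a	id_b	r2
rs719316	rs17603856	0.147503
rs719316	rs909788	0.115615
rs17603856	rs909788	0.074202
rs719316	rs6459480	0.146576
rs17603856	rs6459480	0.142171
rs909788	rs6459480	0.803018
rs719316	rs9297016	0.102584
rs17603856	rs9297016	0.070997
rs909788	rs9297016	0.836365
rs6459480	rs9297016	0.824588
rs719316	rs7772172	0.125319
rs17603856	rs7772172	0.074586
rs909788	rs7772172	0.837604
rs6459480	rs7772172	0.798966
rs9297016	rs7772172	0.761662
rs719316	rs6459472	0.120791
rs17603856	rs6459472	0.14287
rs909788	rs6459472	0.149998
rs6459480	rs6459472	0.123683
rs9297016	rs6459472	0.068139
rs7772172	rs6459472	0.074836
rs719316	rs9367926	0.143029
rs17603856	rs9367926	0.121963
rs909788	rs9367926	0.105693
rs6459480	rs9367926	0.12081
rs9297016	rs9367926	0.069702
rs7772172	rs9367926	0.054984
rs6459472	rs9367926	0.061504
rs719316	rs6915310	0.137876
rs17603856	rs6915310	0.142371
rs909788	rs6915310	0.142345
rs6459480	rs6915310	0.099179
rs9297016	rs6915310	0.138758
rs7772172	rs6915310	0.094243
rs6459472	rs6915310	0.136794
rs9367926	rs6915310	0.80848
rs719316	rs2237199	0.055185
rs17603856	rs2237199	0.090174
rs909788	rs2237199	0.056103
rs6459480	rs2237199	0.059986
rs9297016	rs2237199	0.142397
rs7772172	rs2237199	0.091232
rs6459472	rs2237199	0.100335
rs9367926	rs2237199	0.136733
rs6915310	rs2237199	0.11934
rs719316	rs7770062	0.107637
rs17603856	rs7770062	0.100561
rs909788	rs7770062	0.126014
rs6459480	rs7770062	0.14254
rs9297016	rs7770062	0.070145
rs7772172	rs7770062	0.08473
rs6459472	rs7770062	0.145866
rs9367926	rs7770062	0.125304
rs6915310	rs7770062	0.143835
rs2237199	rs7770062	0.053334
rs719316	rs73366713	0.111088
rs17603856	rs73366713	0.07519
rs909788	rs73366713	0.138432
rs6459480	rs73366713	0.090424
rs9297016	rs73366713	0.060171
rs7772172	rs73366713	0.104027
rs6459472	rs73366713	0.147156
rs9367926	rs73366713	0.062902
rs6915310	rs73366713	0.126192
rs2237199	rs73366713	0.134583
rs7770062	rs73366713	0.799237
rs719316	rs3819405	0.100484
rs17603856	rs3819405	0.110989
rs909788	rs3819405	0.119215
rs6459480	rs3819405	0.059786
rs9297016	rs3819405	0.141258
rs7772172	rs3819405	0.085473
rs6459472	rs3819405	0.100847
rs9367926	rs3819405	0.133481
rs6915310	rs3819405	0.056759
rs2237199	rs3819405	0.133327
rs7770062	rs3819405	0.120186
rs73366713	rs3819405	0.134442
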