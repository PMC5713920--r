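energy_mev	pe	incoherent	pair	total	muen
0.01	5.305675	0.2123216	0	5.517997	5.309659
0.015	1.572052	0.2085066	0	1.780559	1.577803
0.02	0.6632094	0.2048682	0	0.8680776	0.670595
0.03	0.1965065	0.1980745	0	0.394581	0.2068141
0.04	0.08290118	0.1918568	0	0.274758	0.09573285
0.05	0.0424454	0.1861445	0	0.2285899	0.05746872
0.06	0.02456331	0.1808778	0	0.2054411	0.04149876
0.08	0.01036265	0.1714847	0	0.1818473	0.03044838
0.1	0.005305675	0.1633505	0	0.1686561	0.02784859
0.15	0.001572052	0.1470591	0	0.1486312	0.02827222
0.2	0.0006632094	0.1347525	0	0.1354157	0.02981722
0.3	0.0001965065	0.1171719	0	0.1173684	0.03179241
0.4	8.290118e-05	0.1049821	0	0.105065	0.03258815
0.5	4.24454e-05	0.09586118	0	0.09590363	0.03276625
0.6	2.456331e-05	0.0886777	0	0.08870226	0.03261498
0.8	1.036265e-05	0.07789123	0	0.07790159	0.03184142
1	5.305675e-06	0.07001727	0	0.07002258	0.0308159
1.1	3.986232e-06	0.06679081	2.955268e-05	0.06682435	0.03027618
1.25	2.716506e-06	0.0625953	8.638316e-05	0.0626844	0.02947441
1.5	1.572052e-06	0.05687906	0.0001811006	0.05706173	0.02819642
1.75	9.899802e-07	0.05229757	0.0003342511	0.05263281	0.02704002
2	6.632094e-07	0.0485193	0.0004874016	0.04900736	0.02599496
2.5	3.395632e-07	0.04260713	0.0008437984	0.04345127	0.02423562
3	1.965065e-07	0.03815376	0.001200195	0.03935415	0.02281857
3.5	1.237475e-07	0.03465353	0.001560526	0.03621418	0.02167323
4	8.290118e-08	0.03181622	0.001920857	0.03373716	0.02074056
4.5	5.822415e-08	0.0294615	0.002247332	0.03170889	0.01995172
5	4.24454e-08	0.02747059	0.002573807	0.03004444	0.01929912
5.5	3.188986e-08	0.02576167	0.002875148	0.02863685	0.01873807
6	2.456331e-08	0.02427628	0.003176488	0.0274528	0.01826946
6.5	1.931971e-08	0.02297148	0.003435696	0.02640719	0.01784317
7	1.546844e-08	0.02181487	0.003694904	0.02550979	0.01748209
7.5	1.257642e-08	0.02078157	0.003954112	0.0247357	0.01717699
8	1.036265e-08	0.01985208	0.00421332	0.02406541	0.01692034
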