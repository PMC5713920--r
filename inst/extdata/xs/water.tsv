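energy_mev	pe	incoherent	pair	total	muen
0.01	4.99	0.2140978	0	5.204098	4.994017
0.015	1.478519	0.2102509	0	1.688769	1.484317
0.02	0.62375	0.2065821	0	0.8303321	0.6311974
0.03	0.1848148	0.1997316	0	0.3845464	0.1952086
0.04	0.07796875	0.1934619	0	0.2714306	0.09090777
0.05	0.03992	0.1877018	0	0.2276218	0.055069
0.06	0.02310185	0.182391	0	0.2054928	0.04017898
0.08	0.009746094	0.1729193	0	0.1826654	0.02999986
0.1	0.00499	0.164717	0	0.169707	0.02772151
0.15	0.001478519	0.1482894	0	0.1497679	0.02840206
0.2	0.00062375	0.1358799	0	0.1365036	0.03002166
0.3	0.0001848148	0.1181521	0	0.1183369	0.03204505
0.4	7.796875e-05	0.1058603	0	0.1059383	0.03285515
0.5	3.992e-05	0.09666315	0	0.09670307	0.03303749
0.6	2.310185e-05	0.08941957	0	0.08944267	0.03288616
0.8	9.746094e-06	0.07854286	0	0.07855261	0.0321071
1	4.99e-06	0.07060303	0	0.07060802	0.03107335
1.1	3.749061e-06	0.06734958	2.996308e-05	0.06738329	0.03052921
1.25	2.55488e-06	0.06311897	8.758275e-05	0.06320911	0.02972089
1.5	1.478519e-06	0.05735491	0.0001836155	0.05754	0.02843252
1.75	9.310787e-07	0.05273509	0.0003388928	0.05307491	0.02726694
2	6.2375e-07	0.04892521	0.0004941701	0.04942	0.0262137
2.5	3.1936e-07	0.04296358	0.0008555162	0.04381942	0.0244411
3	1.848148e-07	0.03847295	0.001216862	0.03969	0.02301382
3.5	1.163848e-07	0.03494344	0.001582197	0.03652575	0.02186064
4	7.796875e-08	0.03208239	0.001947532	0.03403	0.02092196
4.5	5.475995e-08	0.02970797	0.002278541	0.03198657	0.02012822
5	3.992e-08	0.02770041	0.002609549	0.03031	0.01947187
5.5	2.999249e-08	0.02597719	0.002915075	0.02889229	0.01890775
6	2.310185e-08	0.02447938	0.0032206	0.0277	0.01843685
6.5	1.817023e-08	0.02316365	0.003483407	0.02664708	0.01800843
7	1.45481e-08	0.02199738	0.003746215	0.0257436	0.01764576
7.5	1.182815e-08	0.02095543	0.004009022	0.02496447	0.01733955
8	9.746094e-09	0.02001816	0.00427183	0.02429	0.01708218
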