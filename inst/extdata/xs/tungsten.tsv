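energy_mev	pe	incoherent	pair	total	muen
0.01	10885.62	0.1552536	0	10885.78	10885.63
0.015	3225.37	0.152464	0	3225.523	3225.375
0.02	1360.703	0.1498035	0	1360.853	1360.709
0.03	403.1713	0.1448359	0	403.3161	403.1788
0.04	170.0879	0.1402894	0	170.2282	170.0973
0.05	87.085	0.1361124	0	87.22111	87.09598
0.06	50.39641	0.1322613	0	50.52867	50.40879
0.08	21.26099	0.1253929	0	21.38638	21.27567
0.1	10.88562	0.119445	0	11.00507	10.90211
0.15	3.22537	0.1075324	0	3.332903	3.244894
0.2	1.360703	0.09853361	0	1.459237	1.382021
0.3	0.4031713	0.0856783	0	0.4888496	0.4262748
0.4	0.1700879	0.07676489	0	0.2468528	0.1938563
0.5	0.087085	0.07009552	0	0.1571805	0.1110133
0.6	0.05039641	0.06484282	0	0.1152392	0.07422714
0.8	0.02126099	0.05695555	0	0.07821654	0.04453646
1	0.01088562	0.05119797	0	0.06208359	0.03341492
1.1	0.008178531	0.04883872	0.0002436111	0.05726086	0.03032988
1.25	0.00557344	0.04577088	0.0007120807	0.0520564	0.02724207
1.5	0.00322537	0.04159105	0.001492863	0.04630929	0.02427551
1.75	0.002031137	0.03824098	0.002755326	0.04302744	0.02284714
2	0.001360703	0.03547823	0.004017788	0.04085673	0.02215865
2.5	0.00069668	0.03115515	0.006955668	0.0388075	0.0221654
3	0.0004031713	0.02789876	0.009893548	0.03819548	0.02303292
3.5	0.0002538921	0.02533932	0.01286386	0.03845707	0.02440141
4	0.0001700879	0.02326463	0.01583417	0.03926888	0.02607876
4.5	0.0001194582	0.02154281	0.01852539	0.04018766	0.02775649
5	8.7085e-05	0.02008702	0.02121662	0.04139072	0.02958155
5.5	6.542825e-05	0.01883742	0.02370065	0.0426035	0.03135198
6	5.039641e-05	0.01775128	0.02618469	0.04398637	0.03320685
6.5	3.963814e-05	0.01679718	0.02832141	0.04515823	0.03483807
7	3.173652e-05	0.01595145	0.03045814	0.04644133	0.0365189
7.5	2.580296e-05	0.01519588	0.03259486	0.04781655	0.03824188
8	2.126099e-05	0.01451622	0.03473158	0.04926906	0.04000108
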