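energy_mev	pe	incoherent	pair	total	muen
0.01	5.250276	0.2121207	0	5.462397	5.254256
0.015	1.555637	0.2083093	0	1.763947	1.561382
0.02	0.6562845	0.2046743	0	0.8609588	0.6636631
0.03	0.1944547	0.1978871	0	0.3923418	0.2047525
0.04	0.08203556	0.1916753	0	0.2737109	0.0948551
0.05	0.04200221	0.1859684	0	0.2279706	0.05701131
0.06	0.02430683	0.1807067	0	0.2050135	0.04122626
0.08	0.01025445	0.1713224	0	0.1815769	0.03032118
0.1	0.005250276	0.1631959	0	0.1684462	0.02777186
0.15	0.001555637	0.14692	0	0.1484756	0.02823054
0.2	0.0006562845	0.134625	0	0.1352813	0.02978271
0.3	0.0001944547	0.117061	0	0.1172555	0.03176047
0.4	8.203556e-05	0.1048827	0	0.1049648	0.03255653
0.5	4.200221e-05	0.09577049	0	0.09581249	0.03273485
0.6	2.430683e-05	0.0885938	0	0.08861811	0.03258389
0.8	1.025445e-05	0.07781754	0	0.07782779	0.0318112
1	5.250276e-06	0.06995103	0	0.06995628	0.0307867
1.1	3.94461e-06	0.06672762	2.928879e-05	0.06676086	0.03024748
1.25	2.688141e-06	0.06253608	8.561179e-05	0.06262438	0.02944637
1.5	1.555637e-06	0.05682525	0.0001794835	0.05700629	0.02816926
1.75	9.796433e-07	0.05224809	0.0003312663	0.05258033	0.02701332
2	6.562845e-07	0.04847339	0.0004830492	0.0489571	0.02596846
2.5	3.360177e-07	0.04256682	0.0008362636	0.04340342	0.0242087
3	1.944547e-07	0.03811766	0.001189478	0.03930734	0.02279066
3.5	1.224554e-07	0.03462074	0.001546591	0.03616746	0.0216439
4	8.203556e-08	0.03178612	0.001903704	0.0336899	0.02070952
4.5	5.76162e-08	0.02943363	0.002227264	0.03166095	0.01991898
5	4.200221e-08	0.0274446	0.002550824	0.02999547	0.01926451
5.5	3.155688e-08	0.02573729	0.002849474	0.0285868	0.01870165
6	2.430683e-08	0.02425332	0.003148123	0.02740146	0.01823113
6.5	1.911798e-08	0.02294974	0.003405017	0.02635478	0.01780317
7	1.530693e-08	0.02179423	0.00366191	0.02545616	0.01744036
7.5	1.24451e-08	0.02076191	0.003918803	0.02468073	0.01713348
8	1.025445e-08	0.0198333	0.004175697	0.024009	0.01687499
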