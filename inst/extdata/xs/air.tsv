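energy_mev	pe	incoherent	pair	total	muen
0.01	5.084131	0.1925324	0	5.276664	5.087744
0.015	1.506409	0.189073	0	1.695482	1.511624
0.02	0.6355164	0.1857737	0	0.8212901	0.6422136
0.03	0.1883012	0.1796132	0	0.3679144	0.197648
0.04	0.07943955	0.173975	0	0.2534146	0.09107526
0.05	0.04067305	0.1687951	0	0.2094682	0.05429614
0.06	0.02353765	0.1640193	0	0.1875569	0.03889465
0.08	0.009929944	0.1555016	0	0.1654316	0.02814361
0.1	0.005084131	0.1481256	0	0.1532097	0.02552596
0.15	0.001506409	0.1333526	0	0.1348591	0.02571802
0.2	0.0006355164	0.1221931	0	0.1228286	0.02707226
0.3	0.0001883012	0.106251	0	0.1064393	0.02883935
0.4	7.943955e-05	0.09519734	0	0.09527678	0.02955507
0.5	4.067305e-05	0.08692655	0	0.08696723	0.0297145
0.6	2.353765e-05	0.0804126	0	0.08043613	0.0295764
0.8	9.929944e-06	0.07063147	0	0.0706414	0.02887421
1	5.084131e-06	0.0634914	0	0.06349648	0.02794402
1.1	3.819783e-06	0.06056565	3.005332e-05	0.06059953	0.02745476
1.25	2.603075e-06	0.05676118	8.784654e-05	0.05685163	0.02672916
1.5	1.506409e-06	0.05157771	0.0001841686	0.05176339	0.02557484
1.75	9.486426e-07	0.04742323	0.0003399135	0.0477641	0.02453516
2	6.355164e-07	0.04399711	0.0004956584	0.04449341	0.02359842
2.5	3.253844e-07	0.03863599	0.0008580929	0.0394944	0.02203173
3	1.883012e-07	0.03459768	0.001220527	0.0358184	0.02077896
3.5	1.185803e-07	0.03142369	0.001586962	0.03301077	0.0197749
4	7.943955e-08	0.02885082	0.001953398	0.0308043	0.01896498
4.5	5.579294e-08	0.02671557	0.002285403	0.02900103	0.01828346
5	4.067305e-08	0.02491023	0.002617409	0.02752768	0.01772591
5.5	3.055826e-08	0.02336058	0.002923855	0.02628447	0.01724945
6	2.353765e-08	0.02201364	0.0032303	0.02524396	0.01685696
6.5	1.8513e-08	0.02083045	0.003493899	0.02432436	0.01649904
7	1.482254e-08	0.01978164	0.003757498	0.02353916	0.01620025
7.5	1.205127e-08	0.01884465	0.004021097	0.02286576	0.01595221
8	9.929944e-09	0.01800179	0.004284696	0.0222865	0.01574809
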