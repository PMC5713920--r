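energy_mev	pe	incoherent	pair	total	muen
0.01	39.38503	0.1985535	0	39.58358	39.38875
0.015	11.66964	0.1949858	0	11.86462	11.67502
0.02	4.923128	0.1915834	0	5.114712	4.930035
0.03	1.458705	0.1852303	0	1.643935	1.468344
0.04	0.615391	0.1794158	0	0.7948068	0.6273906
0.05	0.3150802	0.1740739	0	0.4891541	0.3291293
0.06	0.1823381	0.1691487	0	0.3514868	0.1981753
0.08	0.07692388	0.1603647	0	0.2372885	0.09570714
0.1	0.03938503	0.1527579	0	0.192143	0.06046613
0.15	0.01166964	0.137523	0	0.1491926	0.03663842
0.2	0.004923128	0.1260144	0	0.1309376	0.03218663
0.3	0.001458705	0.1095738	0	0.1110325	0.03100576
0.4	0.000615391	0.09817445	0	0.09878984	0.03101282
0.5	0.0003150802	0.08964502	0	0.0899601	0.03091689
0.6	0.0001823381	0.08292735	0	0.08310968	0.03065941
0.8	7.692388e-05	0.07284033	0	0.07291726	0.02984388
1	3.938503e-05	0.06547697	0	0.06551635	0.02885205
1.1	2.959055e-05	0.06245973	4.43294e-05	0.06253365	0.02833995
1.25	2.016513e-05	0.05853628	0.0001295758	0.05868602	0.02758965
1.5	1.166964e-05	0.05319071	0.0002716532	0.05347403	0.0264108
1.75	7.34881e-06	0.0489063	0.0005013809	0.04941503	0.02537156
2	4.923128e-06	0.04537304	0.0007311086	0.04610907	0.02444823
2.5	2.520642e-06	0.03984425	0.001265708	0.04111248	0.02294803
3	1.458705e-06	0.03567966	0.001800308	0.03748143	0.02178715
3.5	9.186012e-07	0.0324064	0.002340809	0.03474813	0.0208927
4	6.15391e-07	0.02975308	0.00288131	0.032635	0.02020396
4.5	4.322088e-07	0.02755105	0.003371027	0.03092251	0.01963945
5	3.150802e-07	0.02568925	0.003860743	0.02955031	0.0192046
5.5	2.367244e-07	0.02409114	0.004312758	0.02840413	0.01884547
6	1.823381e-07	0.02270208	0.004764773	0.02746703	0.01857357
6.5	1.434138e-07	0.02148188	0.005153588	0.02663561	0.01832179
7	1.148251e-07	0.02040028	0.005542404	0.0259428	0.01813094
7.5	9.33571e-08	0.01943398	0.005931219	0.02536529	0.01799238
8	7.692388e-08	0.01856476	0.006320034	0.02488487	0.01789909
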