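energy_keV,mu_rho,mu_tr_rho
5,42.58,41.56
5.5,31.9834,31.1084
6,24.63,23.88
6.5,19.3614,18.6991
7,15.4938,14.9102
7.5,12.591,12.0763
8,10.37,9.915
8.5,8.65418,8.20703
9,7.29733,6.8671
9.5,6.21023,5.8016
10,5.329,4.944
10.5,4.63555,4.23802
11,4.05857,3.65899
11.5,3.57448,3.17977
12,3.16519,2.77988
12.5,2.81671,2.44365
13,2.5181,2.15898
13.5,2.26068,1.91641
14,2.03756,1.70848
14.5,1.84317,1.52926
15,1.673,1.374
15.5,1.54016,1.23792
16,1.4216,1.11902
16.5,1.31541,1.01468
17,1.21997,0.92277
17.5,1.13393,0.841496
18,1.05613,0.769376
18.5,0.98559,0.705165
19,0.921456,0.647818
19.5,0.863003,0.596447
20,0.8096,0.5503
20.5,0.772605,0.509574
21,0.738133,0.472738
21.5,0.705956,0.439339
22,0.675875,0.408989
22.5,0.647708,0.381348
23,0.621297,0.356122
23.5,0.596496,0.333055
24,0.573177,0.311922
24.5,0.551222,0.292525
25,0.530527,0.27469
25.5,0.510996,0.258264
26,0.492542,0.243111
26.5,0.475088,0.229111
27,0.458561,0.216156
27.5,0.442897,0.204152
28,0.428036,0.193014
28.5,0.413924,0.182664
29,0.40051,0.173035
29.5,0.38775,0.164065
30,0.3756,0.1557
30.5,0.36841,0.148645
31,0.36147,0.142017
31.5,0.35477,0.135783
32,0.348296,0.129915
32.5,0.342038,0.124386
33,0.335985,0.119171
33.5,0.330129,0.114248
34,0.324458,0.109597
34.5,0.318966,0.105199
35,0.313644,0.101037
35.5,0.308484,0.0970959
36,0.30348,0.09336
36.5,0.298624,0.0898165
37,0.29391,0.086453
37.5,0.289333,0.0832581
38,0.284886,0.0802212
38.5,0.280564,0.0773327
39,0.276362,0.0745835
39.5,0.272276,0.0719652
40,0.2683,0.06947
40.5,0.265808,0.0675714
41,0.26337,0.065747
41.5,0.260983,0.063993
42,0.258646,0.0623061
42.5,0.256357,0.0606828
43,0.254115,0.05912
43.5,0.251918,0.0576149
44,0.249765,0.0561646
44.5,0.247654,0.0547667
45,0.245585,0.0534185
45.5,0.243555,0.0521179
46,0.241564,0.0508627
46.5,0.239611,0.0496508
47,0.237694,0.0484802
47.5,0.235812,0.0473492
48,0.233965,0.046256
48.5,0.232151,0.045199
49,0.230369,0.0441767
49.5,0.228619,0.0431875
50,0.2269,0.04223
50.5,0.225701,0.0415884
51,0.224519,0.0409627
51.5,0.223355,0.0403524
52,0.222209,0.039757
52.5,0.221079,0.0391759
53,0.219966,0.0386087
53.5,0.218868,0.0380549
54,0.217786,0.0375141
54.5,0.21672,0.0369859
55,0.215668,0.0364698
55.5,0.214631,0.0359655
56,0.213608,0.0354726
56.5,0.212599,0.0349907
57,0.211603,0.0345196
57.5,0.210621,0.0340588
58,0.209652,0.0336081
58.5,0.208696,0.0331672
59,0.207752,0.0327357
59.5,0.20682,0.0323134
60,0.2059,0.0319
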