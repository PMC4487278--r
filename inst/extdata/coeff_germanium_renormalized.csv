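energy_keV,mu_rho,mu_tr_rho
5,215.345,210.87
5.5,168.086,164.552
6,134.059,131.211
6.5,107.93,105.594
7,88.3015,86.3576
7.5,73.2508,71.6129
8,61.5031,60.1079
8.5,52.2549,51.0391
9,44.813,43.7457
9.5,38.7517,37.8085
10,33.7611,32.9225
10.5,29.4602,28.7065
11,25.8708,25.1905
11.1,25.2251,24.5582
11.11,184.305,106.656
11.5,166.29,98.5087
12,146.475,89.3111
12.5,129.65,80.7938
13,115.308,73.3766
13.5,103.008,66.8831
14,92.3976,61.17
14.5,83.1973,56.1205
15,75.18,51.6384
15.5,68.2092,47.4118
16,62.0763,43.6494
16.5,56.6589,40.2879
17,51.8555,37.2743
17.5,47.5814,34.564
18,43.7655,32.119
18.5,40.348,29.907
19,37.2781,27.9004
19.5,34.5127,26.0755
20,32.0149,24.4116
20.5,29.7701,22.8197
21,27.7312,21.3663
21.5,25.8752,20.0365
22,24.1819,18.8172
22.5,22.6338,17.6971
23,21.2156,16.6661
23.5,19.9141,15.7155
24,18.7173,14.8374
24.5,17.615,14.025
25,16.5979,13.2721
25.5,15.658,12.5735
26,14.7881,11.9241
26.5,13.9817,11.3196
27,13.2332,10.7563
27.5,12.5374,10.2306
28,11.8898,9.73936
28.5,11.2863,9.2798
29,10.7231,8.84936
29.5,10.1969,8.44574
30,9.70476,8.06686
30.5,9.25781,7.70727
31,8.83824,7.36918
31.5,8.44395,7.05098
32,8.07306,6.75121
32.5,7.72385,6.46854
33,7.39474,6.20176
33.5,7.0843,5.94975
34,6.79121,5.71149
34.5,6.51428,5.48604
35,6.25238,5.27254
35.5,6.00452,5.07021
36,5.76975,4.87832
36.5,5.54722,4.69618
37,5.33614,4.52319
37.5,5.13576,4.35877
38,4.94542,4.20238
38.5,4.7645,4.05354
39,4.5924,3.9118
39.5,4.4286,3.77672
40,4.27261,3.64792
40.5,4.13098,3.52703
41,3.99571,3.41156
41.5,3.86643,3.30119
42,3.74282,3.19566
42.5,3.62455,3.0947
43,3.51134,2.99804
43.5,3.40292,2.90548
44,3.29903,2.81678
44.5,3.19944,2.73175
45,3.10393,2.65019
45.5,3.01227,2.57193
46,2.92429,2.49679
46.5,2.83978,2.42463
47,2.75859,2.3553
47.5,2.68055,2.28865
48,2.6055,2.22455
48.5,2.5333,2.16289
49,2.46381,2.10354
49.5,2.39691,2.0464
50,2.33247,1.99137
50.5,2.27351,1.93931
51,2.2166,1.88911
51.5,2.16165,1.84068
52,2.10858,1.79395
52.5,2.0573,1.74883
53,2.00774,1.70525
53.5,1.95982,1.66316
54,1.91348,1.62248
54.5,1.86865,1.58316
55,1.82527,1.54514
55.5,1.78327,1.50837
56,1.74261,1.47279
56.5,1.70323,1.43835
57,1.66507,1.40501
57.5,1.62809,1.37273
58,1.59225,1.34146
58.5,1.55749,1.31116
59,1.52378,1.28179
59.5,1.49108,1.25332
60,1.45934,1.22572
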