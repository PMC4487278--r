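energy_keV,mu_rho,mu_tr_rho
5,39.0678,38.1308
5.5,29.4231,28.6161
6,22.7136,22.0191
6.5,17.8886,17.2526
7,14.3405,13.7646
7.5,11.6732,11.1544
8,9.62919,9.16271
8.5,8.04618,7.59825
9,6.79295,6.36872
9.5,5.7878,5.38937
10,4.97218,4.59985
10.5,4.32803,3.94881
11,3.79182,3.41408
11.5,3.34172,2.97092
12,2.961,2.60063
12.5,2.63672,2.28891
13,2.35872,2.02466
13.5,2.11898,1.79924
14,1.91109,1.6058
14.5,1.72991,1.43889
15,1.57125,1.29414
15.5,1.44627,1.16713
16,1.33477,1.05605
16.5,1.23494,0.95849
17,1.14527,0.872466
17.5,1.06445,0.796332
18,0.991406,0.728716
18.5,0.925198,0.668467
19,0.865027,0.614614
19.5,0.810205,0.566336
20,0.760136,0.522934
20.5,0.724777,0.484489
21,0.691867,0.449699
21.5,0.661184,0.418141
22,0.632531,0.38945
22.5,0.605731,0.36331
23,0.580628,0.339443
23.5,0.557081,0.31761
24,0.534962,0.297599
24.5,0.514159,0.279224
25,0.494568,0.262323
25.5,0.476097,0.246752
26,0.458661,0.232381
26.5,0.442184,0.2191
27,0.426597,0.206806
27.5,0.411836,0.19541
28,0.397845,0.184832
28.5,0.384569,0.175
29,0.371961,0.16585
29.5,0.359976,0.157324
30,0.348575,0.149369
30.5,0.34167,0.142588
31,0.335012,0.136218
31.5,0.328589,0.130229
32,0.32239,0.124593
32.5,0.316402,0.119283
33,0.310615,0.114276
33.5,0.305021,0.109551
34,0.299609,0.105088
34.5,0.294372,0.100868
35,0.2893,0.096876
35.5,0.284387,0.093096
36,0.279626,0.089514
36.5,0.27501,0.0861172
37,0.270532,0.0828937
37.5,0.266187,0.0798324
38,0.261969,0.0769232
38.5,0.257873,0.0741566
39,0.253893,0.0715241
39.5,0.250025,0.0690174
40,0.246264,0.0666292
40.5,0.243881,0.0647725
41,0.241549,0.0629898
41.5,0.239268,0.0612773
42,0.237036,0.0596316
42.5,0.234851,0.0580492
43,0.232711,0.056527
43.5,0.230616,0.055062
44,0.228563,0.0536515
44.5,0.226551,0.0522929
45,0.22458,0.0509837
45.5,0.222648,0.0497216
46,0.220753,0.0485044
46.5,0.218895,0.0473301
47,0.217072,0.0461967
47.5,0.215284,0.0451023
48,0.213529,0.0440453
48.5,0.211806,0.0430241
49,0.210115,0.0420369
49.5,0.208455,0.0410825
50,0.206824,0.0401593
50.5,0.205677,0.0395201
51,0.204548,0.0388975
51.5,0.203436,0.0382908
52,0.202341,0.0376995
52.5,0.201262,0.037123
53,0.200199,0.0365609
53.5,0.199152,0.0360126
54,0.198119,0.0354777
54.5,0.197102,0.0349558
55,0.196099,0.0344464
55.5,0.19511,0.0339491
56,0.194135,0.0334635
56.5,0.193173,0.0329892
57,0.192225,0.032526
57.5,0.191289,0.0320733
58,0.190367,0.031631
58.5,0.189456,0.0311986
59,0.188558,0.0307759
59.5,0.187671,0.0303626
60,0.186796,0.0299584
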