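energy_keV,mu_rho,mu_tr_rho
5,40.27,39.31
5.5,30.327,29.501
6,23.41,22.7
6.5,18.4359,17.7861
7,14.778,14.1903
7.5,12.0282,11.4993
8,9.921,9.446
8.5,8.28904,7.83315
9,6.99707,6.56559
9.5,5.96084,5.55594
10,5.12,4.742
10.5,4.45595,4.07082
11,3.90316,3.51955
11.5,3.43915,3.06268
12,3.04667,2.68093
12.5,2.71236,2.35956
13,2.42578,2.08714
13.5,2.17863,1.85474
14,1.96433,1.65531
14.5,1.77756,1.48323
15,1.614,1.334
15.5,1.48516,1.20306
16,1.37023,1.08854
16.5,1.26732,0.987959
17,1.17488,0.899269
17.5,1.09158,0.820776
18,1.01628,0.751065
18.5,0.948036,0.688948
19,0.886014,0.633425
19.5,0.829507,0.583649
20,0.7779,0.5389
20.5,0.741457,0.499261
21,0.707539,0.463391
21.5,0.675917,0.430853
22,0.646387,0.401271
22.5,0.618769,0.374317
23,0.592899,0.349709
23.5,0.568633,0.327196
24,0.54584,0.306562
24.5,0.524403,0.287615
25,0.504216,0.270187
25.5,0.485182,0.254129
26,0.467217,0.239311
26.5,0.45024,0.225614
27,0.43418,0.212936
27.5,0.418972,0.201184
28,0.404557,0.190275
28.5,0.39088,0.180135
29,0.377891,0.170698
29.5,0.365545,0.161904
30,0.3538,0.1537
30.5,0.346691,0.146705
31,0.339836,0.140135
31.5,0.333224,0.133957
32,0.326841,0.128142
32.5,0.320677,0.122664
33,0.314721,0.117499
33.5,0.308962,0.112624
34,0.303392,0.108019
34.5,0.298001,0.103666
35,0.292781,0.0995465
35.5,0.287726,0.095646
36,0.282826,0.0919498
36.5,0.278075,0.0884444
37,0.273468,0.0851177
37.5,0.268997,0.0819583
38,0.264657,0.0789557
38.5,0.260442,0.0761003
39,0.256348,0.0733829
39.5,0.252368,0.0707954
40,0.2485,0.06833
40.5,0.246051,0.0664126
41,0.243656,0.0645715
41.5,0.241312,0.0628029
42,0.239019,0.061103
42.5,0.236775,0.0594685
43,0.234577,0.057896
43.5,0.232425,0.0563826
44,0.230317,0.0549253
44.5,0.228251,0.0535216
45,0.226227,0.0521688
45.5,0.224243,0.0508646
46,0.222297,0.0496068
46.5,0.220389,0.0483931
47,0.218518,0.0472217
47.5,0.216682,0.0460905
48,0.214881,0.0449979
48.5,0.213113,0.0439421
49,0.211377,0.0429215
49.5,0.209673,0.0419346
50,0.208,0.04098
50.5,0.206825,0.0403182
51,0.205669,0.0396735
51.5,0.20453,0.0390452
52,0.203409,0.0384328
52.5,0.202304,0.0378357
53,0.201216,0.0372535
53.5,0.200143,0.0366855
54,0.199087,0.0361314
54.5,0.198045,0.0355906
55,0.197018,0.0350627
55.5,0.196006,0.0345474
56,0.195008,0.0340441
56.5,0.194024,0.0335526
57,0.193054,0.0330723
57.5,0.192097,0.0326031
58,0.191153,0.0321445
58.5,0.190221,0.0316962
59,0.189302,0.0312579
59.5,0.188395,0.0308292
60,0.1875,0.03041
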