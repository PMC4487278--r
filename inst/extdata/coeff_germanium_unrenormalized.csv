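energy_keV,mu_rho,mu_tr_rho
5,222,217.392
5.5,173.279,169.641
6,138.2,135.269
6.5,111.262,108.859
7,91.0271,89.0284
7.5,75.511,73.8277
8,63.4,61.9668
8.5,53.8658,52.6175
9,46.1937,45.0986
9.5,39.9449,38.9777
10,34.8,33.9407
10.5,30.3661,29.5942
11,26.6657,25.9694
11.1,26,25.3177
11.11,190,109.954
11.5,171.428,101.555
12,151,92.0732
12.5,133.655,83.2924
13,118.869,75.6459
13.5,106.188,68.9515
14,95.2501,63.0617
14.5,85.7652,57.856
15,77.5,53.2354
15.5,70.3136,48.878
16,63.9911,44.9992
16.5,58.4061,41.5338
17,53.4541,38.427
17.5,49.0478,35.6329
18,45.114,33.1122
18.5,41.5908,30.8318
19,38.426,28.7632
19.5,35.5751,26.8817
20,33,25.1665
20.5,30.6857,23.5253
21,28.5838,22.027
21.5,26.6704,20.656
22,24.9247,19.399
22.5,23.3288,18.2442
23,21.8668,17.1813
23.5,20.525,16.2013
24,19.2912,15.296
24.5,18.1548,14.4585
25,17.1063,13.6824
25.5,16.1373,12.9621
26,15.2405,12.2926
26.5,14.4092,11.6695
27,13.6376,11.0887
27.5,12.9203,10.5468
28,12.2526,10.0403
28.5,11.6304,9.56656
29,11.0498,9.1228
29.5,10.5073,8.7067
30,10,8.31609
30.5,9.53924,7.94538
31,9.1067,7.59683
31.5,8.70022,7.26879
32,8.31787,6.95974
32.5,7.95787,6.66833
33,7.61859,6.39329
33.5,7.29855,6.13348
34,6.99641,5.88785
34.5,6.71092,5.65543
35,6.44093,5.43533
35.5,6.18541,5.22673
36,5.94339,5.0289
36.5,5.71399,4.84113
37,5.49638,4.66278
37.5,5.28981,4.49327
38,5.0936,4.33205
38.5,4.90708,4.1786
39,4.72967,4.03247
39.5,4.56082,3.89321
40,4.4,3.76042
40.5,4.254,3.63579
41,4.11456,3.51674
41.5,3.98129,3.40297
42,3.85385,3.29417
42.5,3.73194,3.19008
43,3.61523,3.09043
43.5,3.50347,2.995
44,3.39638,2.90356
44.5,3.29371,2.81589
45,3.19525,2.73181
45.5,3.10077,2.65112
46,3.01007,2.57366
46.5,2.92296,2.49927
47,2.83926,2.42779
47.5,2.75881,2.35907
48,2.68144,2.29299
48.5,2.60702,2.22942
49,2.53539,2.16823
49.5,2.46642,2.10932
50,2.4,2.05258
50.5,2.33922,1.99892
51,2.28056,1.94716
51.5,2.22392,1.89723
52,2.16921,1.84905
52.5,2.11635,1.80253
53,2.06526,1.75761
53.5,2.01587,1.71421
54,1.96811,1.67227
54.5,1.9219,1.63173
55,1.87718,1.59254
55.5,1.83389,1.55462
56,1.79198,1.51794
56.5,1.75138,1.48243
57,1.71205,1.44806
57.5,1.67394,1.41478
58,1.63699,1.38253
58.5,1.60116,1.35129
59,1.56642,1.32102
59.5,1.53271,1.29167
60,1.5,1.2632
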