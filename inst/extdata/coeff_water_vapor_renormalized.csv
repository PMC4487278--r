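energy_keV,mu_rho,mu_tr_rho
5,41.3091,40.3133
5.5,31.0304,30.1753
6,23.8976,23.1637
6.5,18.787,18.1382
7,15.0355,14.463
7.5,12.2197,11.7141
8,10.0654,9.61765
8.5,8.40101,7.96092
9,7.08486,6.6612
9.5,6.03036,5.62766
10,5.17555,4.7958
10.5,4.50289,4.11101
11,3.94322,3.54935
11.5,3.47363,3.08452
12,3.07661,2.69663
12.5,2.73858,2.37049
13,2.44891,2.09436
13.5,2.19921,1.85907
14,1.98276,1.65739
14.5,1.79419,1.48355
15,1.62912,1.33295
15.5,1.50025,1.20096
16,1.38524,1.08563
16.5,1.28222,0.984433
17,1.18963,0.895282
17.5,1.10616,0.81645
18,1.03069,0.746498
18.5,0.962252,0.684219
19,0.900032,0.628597
19.5,0.843321,0.578772
20,0.791509,0.534014
20.5,0.755614,0.494515
21,0.722165,0.458789
21.5,0.690943,0.426397
22,0.661753,0.396961
22.5,0.634421,0.370154
23,0.608792,0.34569
23.5,0.584725,0.32332
24,0.562095,0.302825
24.5,0.540788,0.284014
25,0.520704,0.266718
25.5,0.501748,0.250789
26,0.483838,0.236095
26.5,0.466897,0.22252
27,0.450856,0.209958
27.5,0.435652,0.198319
28,0.421227,0.187518
28.5,0.407528,0.177483
29,0.394507,0.168147
29.5,0.382119,0.159451
30,0.370324,0.151341
30.5,0.363339,0.144502
31,0.356599,0.138076
31.5,0.350089,0.132034
32,0.3438,0.126346
32.5,0.33772,0.120986
33,0.33184,0.115931
33.5,0.326149,0.11116
34,0.320639,0.106653
34.5,0.315303,0.102391
35,0.310131,0.0983577
35.5,0.305116,0.0945382
36,0.300253,0.0909182
36.5,0.295533,0.0874847
37,0.290952,0.0842258
37.5,0.286502,0.0811304
38,0.28218,0.0781884
38.5,0.277978,0.0753901
39,0.273893,0.072727
39.5,0.26992,0.0701908
40,0.266055,0.0677741
40.5,0.263629,0.0659359
41,0.261255,0.0641698
41.5,0.258931,0.0624719
42,0.256655,0.0608391
42.5,0.254426,0.0592679
43,0.252242,0.0577555
43.5,0.250103,0.0562989
44,0.248005,0.0548955
44.5,0.245949,0.0535428
45,0.243933,0.0522384
45.5,0.241956,0.0509801
46,0.240016,0.0497658
46.5,0.238112,0.0485935
47,0.236244,0.0474613
47.5,0.23441,0.0463675
48,0.23261,0.0453103
48.5,0.230842,0.0442881
49,0.229106,0.0432996
49.5,0.2274,0.0423432
50,0.225724,0.0414175
50.5,0.224552,0.0407983
51,0.223398,0.0401944
51.5,0.222261,0.0396055
52,0.221141,0.0390309
52.5,0.220037,0.0384702
53,0.218948,0.037923
53.5,0.217876,0.0373888
54,0.216818,0.0368672
54.5,0.215776,0.0363577
55,0.214748,0.03586
55.5,0.213734,0.0353737
56,0.212734,0.0348985
56.5,0.211747,0.0344339
57,0.210773,0.0339797
57.5,0.209813,0.0335356
58,0.208865,0.0331012
58.5,0.20793,0.0326762
59,0.207006,0.0322605
59.5,0.206095,0.0318536
60,0.205195,0.0314553
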