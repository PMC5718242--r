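energy_mev,water,pmma,air,aluminum,titanium,lead
0.010,5.329,3.357,5.120,26.23,110.7,130.6
0.015,1.673,1.101,1.614,7.955,34.80,111.6
0.020,0.8096,0.5714,0.7779,3.441,15.85,86.36
0.030,0.3756,0.3032,0.3538,1.128,4.972,30.32
0.050,0.2269,0.2089,0.2080,0.3681,1.213,8.041
0.080,0.1837,0.1751,0.1662,0.2018,0.4052,2.419
0.100,0.1707,0.1641,0.1541,0.1704,0.2721,5.549
0.150,0.1505,0.1456,0.1356,0.1378,0.1649,2.014
0.200,0.1370,0.1328,0.1233,0.1223,0.1314,0.9985
0.300,0.1186,0.1152,0.1067,0.1042,0.1043,0.4026
0.500,0.0969,0.0941,0.0871,0.0848,0.0828,0.1614
0.800,0.0786,0.0763,0.0707,0.0684,0.0662,0.0887
1.000,0.0707,0.0686,0.0636,0.0614,0.0589,0.0710
1.500,0.0575,0.0559,0.0518,0.0500,0.0484,0.0522
2.000,0.0494,0.0480,0.0445,0.0432,0.0422,0.0457
3.000,0.0397,0.0386,0.0358,0.0353,0.0354,0.0420
4.000,0.0340,0.0329,0.0308,0.0310,0.0320,0.0420
5.000,0.0303,0.0292,0.0275,0.0284,0.0301,0.0426
6.000,0.0277,0.0267,0.0252,0.0266,0.0289,0.0436
8.000,0.0243,0.0232,0.0223,0.0243,0.0276,0.0459
10.000,0.0222,0.0211,0.0204,0.0232,0.0271,0.0489
15.000,0.0191,0.0180,0.0178,0.0214,0.0263,0.0552
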