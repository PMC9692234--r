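energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,257.9474,0.002427606
1.5,192.6318,0.004698465
2,155.5135,0.007606411
3,114.1104,0.01521659
4,91.1838,0.02509052
5,76.45418,0.0371203
7.5,55.28547,0.07614927
10,43.81753,0.1273337
12.5,36.55115,0.1900956
15,31.50454,0.264
17.5,27.78067,0.3486966
20,24.91181,0.4438902
22.5,22.62915,0.5493246
25,20.76677,0.6647724
27.5,19.21646,0.7900288
30,17.90455,0.9249062
32.5,16.77906,1.069232
35,15.80222,1.222845
37.5,14.94594,1.385594
40,14.18881,1.557338
42.5,13.51428,1.737941
45,12.9093,1.927275
47.5,12.36349,2.125219
50,11.86842,2.331654
52.5,11.41723,2.546468
55,11.00423,2.769553
57.5,10.62471,3.000804
60,10.27469,3.240121
62.5,9.950804,3.487405
65,9.650196,3.742562
67.5,9.370407,4.005499
70,9.109315,4.276127
72.5,8.865083,4.554359
75,8.636107,4.840109
77.5,8.420982,5.133296
80,8.218473,5.433838
82.5,8.027489,5.741655
85,7.84706,6.056672
87.5,7.676326,6.378812
90,7.514517,6.708001
92.5,7.360943,7.044166
95,7.214984,7.387238
97.5,7.076083,7.737146
100,6.943734,8.093821
102.5,6.81748,8.457197
105,6.696906,8.827208
107.5,6.581633,9.203789
110,6.471317,9.586877
112.5,6.365642,9.976409
115,6.264319,10.37232
117.5,6.167083,10.77456
120,6.073689,11.18306
122.5,5.983914,11.59776
125,5.897549,12.01861
127.5,5.814402,12.44555
130,5.734296,12.87853
132.5,5.657067,13.31748
135,5.582561,13.76236
137.5,5.510637,14.21311
140,5.441162,14.66968
142.5,5.374012,15.13202
145,5.309073,15.60007
147.5,5.246237,16.07378
150,5.185403,16.55311
152.5,5.126477,17.03801
155,5.06937,17.52843
157.5,5.014,18.02431
160,4.960288,18.52562
162.5,4.908161,19.0323
165,4.85755,19.54431
167.5,4.808389,20.06161
170,4.760618,20.58415
172.5,4.714179,21.11188
175,4.669016,21.64476
177.5,4.625078,22.18276
180,4.582316,22.72581
182.5,4.540683,23.27389
185,4.500136,23.82695
187.5,4.460633,24.38496
190,4.422134,24.94786
192.5,4.384602,25.51562
195,4.348,26.0882
197.5,4.312296,26.66556
200,4.277456,27.24766
202.5,4.24345,27.83447
205,4.210249,28.42594
207.5,4.177823,29.02203
210,4.146148,29.62272
212.5,4.115197,30.22796
215,4.084947,30.83771
217.5,4.055373,31.45195
220,4.026453,32.07064
222.5,3.998167,32.69373
225,3.970494,33.3212
227.5,3.943415,33.95301
230,3.91691,34.58912
232.5,3.890963,35.22951
235,3.865555,35.87414
237.5,3.840671,36.52297
240,3.816295,37.17598
242.5,3.792411,37.83314
245,3.769005,38.4944
247.5,3.746063,39.15973
250,3.723572,39.82912
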