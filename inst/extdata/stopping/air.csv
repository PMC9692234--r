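energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,232.8951,0.002737934
1.5,174.8346,0.005245499
2,141.5791,0.00844402
3,104.2646,0.01678572
4,83.49962,0.02757893
5,70.11829,0.04070492
7.5,50.82791,0.08320097
10,40.34571,0.1388277
12.5,33.6911,0.2069509
15,29.063,0.2870944
17.5,25.64435,0.3788748
20,23.0084,0.4819697
22.5,20.9096,0.5960994
25,19.19621,0.7210161
27.5,17.76921,0.8564965
30,16.5611,1.002337
32.5,15.52426,1.158348
35,14.62405,1.324357
37.5,13.83468,1.500198
40,13.13652,1.685717
42.5,12.51435,1.880769
45,11.95621,2.085213
47.5,11.45254,2.298918
50,10.9956,2.521756
52.5,10.57907,2.753606
55,10.19774,2.994349
57.5,9.847261,3.243873
60,9.52397,3.502068
62.5,9.224778,3.768829
65,8.947047,4.044053
67.5,8.688516,4.32764
70,8.447232,4.619494
72.5,8.2215,4.919519
75,8.009846,5.227625
77.5,7.810973,5.543721
80,7.623743,5.867721
82.5,7.447151,6.199539
85,7.280303,6.539091
87.5,7.122406,6.886296
90,6.97275,7.241075
92.5,6.830699,7.603348
95,6.695681,7.973039
97.5,6.567181,8.350073
100,6.444734,8.734376
102.5,6.327918,9.125876
105,6.216349,9.524502
107.5,6.109679,9.930184
110,6.007589,10.34285
112.5,5.909788,10.76244
115,5.816009,11.18888
117.5,5.726007,11.62212
120,5.639557,12.06207
122.5,5.556452,12.50869
125,5.4765,12.96191
127.5,5.399523,13.42166
130,5.325358,13.88789
132.5,5.253853,14.36055
135,5.184866,14.83956
137.5,5.118266,15.32487
140,5.053932,15.81643
142.5,4.991748,16.31418
145,4.931609,16.81807
147.5,4.873415,17.32803
150,4.817074,17.84402
152.5,4.762497,18.36599
155,4.709603,18.89388
157.5,4.658316,19.42763
160,4.608563,19.96721
162.5,4.560276,20.51255
165,4.513393,21.06362
167.5,4.467852,21.62035
170,4.423596,22.18271
172.5,4.380573,22.75064
175,4.338731,23.32409
177.5,4.298023,23.90303
180,4.258403,24.4874
182.5,4.219829,25.07717
185,4.182259,25.67227
187.5,4.145656,26.27268
190,4.109983,26.87834
192.5,4.075204,27.48921
195,4.041287,28.10526
197.5,4.0082,28.72643
200,3.975914,29.35268
202.5,3.9444,29.98399
205,3.913631,30.62029
207.5,3.883581,31.26156
210,3.854225,31.90775
212.5,3.82554,32.55882
215,3.797503,33.21474
217.5,3.770093,33.87546
220,3.743289,34.54096
222.5,3.717072,35.21118
225,3.691422,35.88609
227.5,3.666323,36.56565
230,3.641755,37.24984
232.5,3.617704,37.93861
235,3.594152,38.63192
237.5,3.571086,39.32974
240,3.54849,40.03204
242.5,3.52635,40.73878
245,3.504652,41.44993
247.5,3.483385,42.16544
250,3.462535,42.8853
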