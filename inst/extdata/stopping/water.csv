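energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,269.6567,0.002328459
1.5,201.5397,0.004499694
2,162.7827,0.007278375
3,119.5122,0.01454633
4,95.53326,0.02397218
5,80.12023,0.03545277
7.5,57.95872,0.0726877
10,45.94723,0.1215049
12.5,38.33414,0.1813522
15,33.04559,0.2518144
17.5,29.14255,0.3325569
20,26.13526,0.423298
22.5,23.74219,0.523793
25,21.78954,0.6338251
27.5,20.16397,0.7531987
30,18.78827,0.881735
32.5,17.60798,1.019269
35,16.58353,1.165648
37.5,15.68546,1.320727
40,14.89135,1.48437
42.5,14.18384,1.65645
45,13.54926,1.836845
47.5,12.97672,2.025436
50,12.45739,2.222113
52.5,11.98408,2.426769
55,11.55082,2.6393
57.5,11.15266,2.859606
60,10.78545,3.087592
62.5,10.44565,3.323163
65,10.13026,3.56623
67.5,9.83671,3.816705
70,9.562771,4.074502
72.5,9.306515,4.339539
75,9.066263,4.611733
77.5,8.84054,4.891008
80,8.628051,5.177284
82.5,8.427651,5.470488
85,8.238325,5.770545
87.5,8.059168,6.077384
90,7.889374,6.390933
92.5,7.72822,6.711125
95,7.575055,7.03789
97.5,7.429295,7.371164
100,7.290408,7.71088
102.5,7.157916,8.056975
105,7.031383,8.409387
107.5,6.910413,8.768053
110,6.794643,9.132913
112.5,6.683742,9.503907
115,6.577407,9.880977
117.5,6.475361,10.26407
120,6.377346,10.65312
122.5,6.283128,11.04807
125,6.192488,11.44888
127.5,6.105225,11.85548
130,6.021153,12.26783
132.5,5.940099,12.68587
135,5.861903,13.10955
137.5,5.786416,13.53882
140,5.713499,13.97363
142.5,5.643022,14.41393
145,5.574864,14.85966
147.5,5.508914,15.31079
150,5.445064,15.76727
152.5,5.383217,16.22904
155,5.323278,16.69606
157.5,5.265162,17.16829
160,5.208786,17.64569
162.5,5.154074,18.1282
165,5.100952,18.61578
167.5,5.049353,19.10839
170,4.999211,19.60599
172.5,4.950468,20.10853
175,4.903063,20.61598
177.5,4.856945,21.12829
180,4.81206,21.64542
182.5,4.768361,22.16733
185,4.725801,22.69399
187.5,4.684337,23.22534
190,4.643926,23.76136
192.5,4.60453,24.30201
195,4.566111,24.84724
197.5,4.528633,25.39702
200,4.492063,25.95131
202.5,4.456368,26.51008
205,4.421517,27.07329
207.5,4.387481,27.6409
210,4.354232,28.21288
212.5,4.321744,28.7892
215,4.28999,29.36981
217.5,4.258946,29.95469
220,4.22859,30.5438
222.5,4.198898,31.1371
225,4.169849,31.73458
227.5,4.141424,32.33618
230,4.113602,32.94188
232.5,4.086365,33.55165
235,4.059694,34.16545
237.5,4.033573,34.78326
240,4.007984,35.40504
242.5,3.982913,36.03076
245,3.958343,36.66039
247.5,3.934261,37.2939
250,3.910651,37.93126
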