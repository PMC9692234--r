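energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,63.61595,0.01117646
1.5,58.12589,0.0193599
2,51.97378,0.02846286
3,42.54863,0.04983438
4,36.13649,0.07543378
5,31.54545,0.105132
7.5,24.25593,0.1964364
10,19.9362,0.3107751
12.5,17.04977,0.4468704
15,14.97089,0.6037455
17.5,13.39494,0.7806142
20,12.15493,0.9768189
22.5,11.15126,1.191794
25,10.3206,1.425043
27.5,9.620688,1.676122
30,9.022144,1.944628
32.5,8.503898,2.230196
35,8.050412,2.532485
37.5,7.64997,2.851181
40,7.293555,3.185987
42.5,6.974112,3.536628
45,6.686039,3.902839
47.5,6.424823,4.284374
50,6.186791,4.680994
52.5,5.968919,5.092473
55,5.768692,5.518596
57.5,5.584005,5.959153
60,5.413077,6.413945
62.5,5.254394,6.882779
65,5.106658,7.365468
67.5,4.968753,7.861833
70,4.83971,8.3717
72.5,4.718683,8.894898
75,4.604936,9.431263
77.5,4.497818,9.980636
80,4.396757,10.54286
82.5,4.301243,11.11779
85,4.210824,11.70527
87.5,4.125097,12.30516
90,4.0437,12.91731
92.5,3.966308,13.5416
95,3.892628,14.17789
97.5,3.822396,14.82604
100,3.755371,15.48593
102.5,3.691336,16.15742
105,3.630092,16.84041
107.5,3.571459,17.53476
110,3.515272,18.24036
112.5,3.461378,18.95709
115,3.409638,19.68483
117.5,3.359925,20.42348
120,3.312121,21.17292
122.5,3.266117,21.93305
125,3.221811,22.70376
127.5,3.179111,23.48494
130,3.137931,24.27649
132.5,3.09819,25.07831
135,3.059814,25.8903
137.5,3.022732,26.71236
140,2.986881,27.5444
142.5,2.952199,28.38632
145,2.918631,29.23802
147.5,2.886123,30.09942
150,2.854625,30.97042
152.5,2.824091,31.85093
155,2.794478,32.74087
157.5,2.765743,33.64015
160,2.73785,34.54868
162.5,2.710761,35.46637
165,2.684441,36.39315
167.5,2.65886,37.32893
170,2.633985,38.27363
172.5,2.609789,39.22717
175,2.586244,40.18946
177.5,2.563323,41.16045
180,2.541004,42.14003
182.5,2.519261,43.12815
185,2.498074,44.12472
187.5,2.477422,45.12966
190,2.457284,46.14292
192.5,2.437642,47.16441
195,2.418478,48.19406
197.5,2.399775,49.2318
200,2.381516,50.27756
202.5,2.363686,51.33128
205,2.34627,52.39288
207.5,2.329254,53.4623
210,2.312624,54.53947
212.5,2.296369,55.62432
215,2.280474,56.7168
217.5,2.26493,57.81683
220,2.249723,58.92435
222.5,2.234844,60.0393
225,2.220283,61.16162
227.5,2.206029,62.29125
230,2.192072,63.42812
232.5,2.178405,64.57217
235,2.165017,65.72335
237.5,2.151902,66.8816
240,2.13905,68.04686
242.5,2.126454,69.21907
245,2.114106,70.39817
247.5,2.102,71.58412
250,2.090128,72.77684
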