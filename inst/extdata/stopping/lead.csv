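energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,55.46333,0.05707345
1.5,52.42268,0.06627272
2,47.5526,0.07628471
3,39.46452,0.09945754
4,33.74951,0.1269513
5,29.58925,0.1586753
7.5,22.89377,0.2556661
10,18.8824,0.3765734
12.5,16.18595,0.5200838
15,14.23631,0.6851828
17.5,12.75421,0.8710502
20,11.58556,1.076999
22.5,10.63805,1.302438
25,9.852792,1.546847
27.5,9.19036,1.809761
30,8.623308,2.090761
32.5,8.131906,2.389462
35,7.701585,2.70551
37.5,7.321342,3.038573
40,6.982703,3.388345
42.5,6.679028,3.754534
45,6.405039,4.136868
47.5,6.156484,4.535085
50,5.929894,4.948939
52.5,5.722416,5.378194
55,5.531675,5.822622
57.5,5.355679,6.282008
60,5.192746,6.756142
62.5,5.041442,7.244824
65,4.900539,7.747858
67.5,4.768978,8.265058
70,4.645841,8.796241
72.5,4.53033,9.341231
75,4.421742,9.899857
77.5,4.319463,10.47195
80,4.222948,11.05736
82.5,4.131715,11.65591
85,4.045333,12.26746
87.5,3.963421,12.89185
90,3.885633,13.52894
92.5,3.811662,14.17859
95,3.741229,14.84066
97.5,3.674082,15.51501
100,3.609993,16.2015
102.5,3.548755,16.90001
105,3.49018,17.6104
107.5,3.434095,18.33256
110,3.380343,19.06635
112.5,3.32878,19.81166
115,3.279272,20.56836
117.5,3.2317,21.33635
120,3.185949,22.1155
122.5,3.141916,22.9057
125,3.099506,23.70685
127.5,3.058629,24.51883
130,3.019204,25.34153
132.5,2.981153,26.17486
135,2.944406,27.0187
137.5,2.908897,27.87296
140,2.874562,28.73753
142.5,2.841346,29.61232
145,2.809193,30.49723
147.5,2.778054,31.39216
150,2.747881,32.29702
152.5,2.718629,33.21171
155,2.690258,34.13615
157.5,2.662727,35.07024
160,2.636,36.01389
162.5,2.610042,36.96702
165,2.58482,37.92954
167.5,2.560304,38.90137
170,2.536465,39.88241
172.5,2.513274,40.87259
175,2.490706,41.87182
177.5,2.468736,42.88002
180,2.447341,43.89712
182.5,2.426499,44.92303
185,2.406188,45.95767
187.5,2.386388,47.00098
190,2.367081,48.05287
192.5,2.348249,49.11326
195,2.329874,50.18209
197.5,2.31194,51.25927
200,2.294432,52.34475
202.5,2.277334,53.43844
205,2.260633,54.54027
207.5,2.244314,55.65019
210,2.228366,56.7681
212.5,2.212776,57.89396
215,2.197532,59.02769
217.5,2.182623,60.16922
220,2.168038,61.31849
222.5,2.153766,62.47543
225,2.139799,63.63998
227.5,2.126126,64.81207
230,2.112738,65.99165
232.5,2.099627,67.17865
235,2.086784,68.37301
237.5,2.074202,69.57466
240,2.061872,70.78355
242.5,2.049788,71.99962
245,2.037942,73.22281
247.5,2.026327,74.45306
250,2.014937,75.69031
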