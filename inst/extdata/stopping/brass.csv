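energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,125.4689,0.008815318
1.5,101.5207,0.0132719
2,85.67744,0.01865524
3,66.11733,0.03207262
4,54.40724,0.04883888
5,46.53657,0.06878373
7.5,34.71583,0.1317667
10,28.03896,0.2124327
12.5,23.69832,0.309819
15,20.62901,0.423207
17.5,18.33328,0.552023
20,16.54557,0.6957881
22.5,15.1106,0.8540905
25,13.93115,1.026568
27.5,12.94312,1.212896
30,12.10241,1.41278
32.5,11.37766,1.62595
35,10.74592,1.852157
37.5,10.18999,2.091168
40,9.696708,2.342764
42.5,9.255834,2.60674
45,8.859265,2.882901
47.5,8.500509,3.171061
50,8.174295,3.471043
52.5,7.876302,3.782679
55,7.602949,4.105806
57.5,7.351243,4.440267
60,7.118662,4.785914
62.5,6.903068,5.142599
65,6.702632,5.510183
67.5,6.515781,5.88853
70,6.341156,6.277507
72.5,6.177574,6.676987
75,6.024004,7.086846
77.5,5.879539,7.50696
80,5.743379,7.937213
82.5,5.614818,8.37749
85,5.493227,8.827677
87.5,5.378046,9.287665
90,5.268775,9.757347
92.5,5.164964,10.23662
95,5.066208,10.72537
97.5,4.972143,11.22352
100,4.882437,11.73094
102.5,4.79679,12.24756
105,4.714931,12.77328
107.5,4.636611,13.30799
110,4.561603,13.85162
112.5,4.489698,14.40407
115,4.420707,14.96525
117.5,4.354455,15.53508
120,4.290779,16.11347
122.5,4.229531,16.70034
125,4.170574,17.29561
127.5,4.113781,17.89919
130,4.059035,18.51101
132.5,4.006224,19.13099
135,3.955249,19.75904
137.5,3.906015,20.3951
140,3.858433,21.03909
142.5,3.812422,21.69094
145,3.767904,22.35057
147.5,3.724808,23.01792
150,3.683067,23.6929
152.5,3.642617,24.37546
155,3.603399,25.06552
157.5,3.565359,25.76301
160,3.528443,26.46788
162.5,3.492602,27.18005
165,3.457791,27.89945
167.5,3.423965,28.62604
170,3.391083,29.35973
172.5,3.359107,30.10047
175,3.327999,30.8482
177.5,3.297725,31.60285
180,3.268252,32.36437
182.5,3.239548,33.1327
185,3.211585,33.90778
187.5,3.184333,34.68955
190,3.157766,35.47795
192.5,3.131859,36.27293
195,3.106588,37.07443
197.5,3.08193,37.88239
200,3.057862,38.69677
202.5,3.034365,39.5175
205,3.011417,40.34454
207.5,2.989001,41.17783
210,2.967098,42.01732
212.5,2.945692,42.86296
215,2.924764,43.7147
217.5,2.904301,44.57249
220,2.884286,45.43627
222.5,2.864706,46.306
225,2.845546,47.18163
227.5,2.826793,48.06312
230,2.808436,48.9504
232.5,2.79046,49.84345
235,2.772856,50.74221
237.5,2.755611,51.64663
240,2.738715,52.55667
242.5,2.722157,53.47229
245,2.705929,54.39344
247.5,2.690019,55.32007
250,2.67442,56.25214
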