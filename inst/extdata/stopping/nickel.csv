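energy_MeV,mass_stopping_power_MeV_cm2_g,csda_range_g_cm2
1,133.8447,0.004642009
1.5,107.886,0.008828986
2,90.86875,0.01390032
3,69.9724,0.02656697
4,57.50997,0.04242015
5,49.15105,0.06129715
7.5,36.62143,0.1209718
10,29.55669,0.197471
12.5,24.96872,0.2898813
15,21.72687,0.3975214
17.5,19.30338,0.5198469
20,17.41698,0.6564039
22.5,15.9033,0.8068016
25,14.65952,0.970696
27.5,13.61785,1.147779
30,12.73168,1.337772
32.5,11.96788,1.540418
35,11.30221,1.755481
37.5,10.71651,1.982738
40,10.19688,2.221984
42.5,9.732513,2.473021
45,9.314856,2.735665
47.5,8.93706,3.009741
50,8.593566,3.295079
52.5,8.279814,3.591519
55,7.992027,3.898906
57.5,7.727051,4.217094
60,7.482225,4.545937
62.5,7.255295,4.885299
65,7.044332,5.235045
67.5,6.84768,5.595047
70,6.663905,5.965178
72.5,6.491761,6.345317
75,6.33016,6.735346
77.5,6.178147,7.135149
80,6.03488,7.544613
82.5,5.899614,7.963629
85,5.771687,8.392091
87.5,5.650509,8.829893
90,5.535553,9.276933
92.5,5.426344,9.733112
95,5.322457,10.19833
97.5,5.223507,10.6725
100,5.129146,11.15551
102.5,5.039058,11.64729
105,4.952957,12.14773
107.5,4.870579,12.65676
110,4.791688,13.17427
112.5,4.716062,13.7002
115,4.643503,14.23445
117.5,4.573825,14.77695
120,4.506859,15.3276
122.5,4.442449,15.88634
125,4.380448,16.45308
127.5,4.320725,17.02775
130,4.263154,17.61027
132.5,4.207621,18.20057
135,4.154019,18.79857
137.5,4.102248,19.4042
140,4.052216,20.01739
142.5,4.003835,20.63807
145,3.957026,21.26617
147.5,3.911713,21.90162
150,3.867825,22.54436
152.5,3.825295,23.19431
155,3.784062,23.85142
157.5,3.744067,24.51562
160,3.705254,25.18685
162.5,3.667573,25.86504
165,3.630975,26.55013
167.5,3.595412,27.24206
170,3.560843,27.94077
172.5,3.527227,28.6462
175,3.494524,29.35829
177.5,3.462697,30.07699
180,3.431713,30.80223
182.5,3.401539,31.53397
185,3.372142,32.27214
187.5,3.343494,33.01669
190,3.315567,33.76756
192.5,3.288333,34.52471
195,3.261768,35.28807
197.5,3.235847,36.0576
200,3.210548,36.83324
202.5,3.185848,37.61495
205,3.161726,38.40267
207.5,3.138164,39.19635
210,3.115141,39.99594
212.5,3.092639,40.8014
215,3.070642,41.61267
217.5,3.049133,42.4297
220,3.028095,43.25246
222.5,3.007514,44.08089
225,2.987375,44.91495
227.5,2.967664,45.75459
230,2.948369,46.59976
232.5,2.929475,47.45042
235,2.910972,48.30653
237.5,2.892846,49.16805
240,2.875087,50.03492
242.5,2.857685,50.90711
245,2.840628,51.78458
247.5,2.823907,52.66727
250,2.807511,53.55516
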