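material,energy_MeV,neutrons_per_proton
tungsten,10,5.39328e-05
tungsten,15,0.000142716
tungsten,20,0.000284659
tungsten,25,0.000486306
tungsten,30,0.000753259
tungsten,35,0.00109048
tungsten,40,0.00150244
tungsten,45,0.00199326
tungsten,50,0.00256674
tungsten,55,0.00322644
tungsten,60,0.00397572
tungsten,65,0.00481776
tungsten,70,0.00575557
tungsten,75,0.00679204
tungsten,80,0.00792993
tungsten,85,0.00917189
tungsten,90,0.0105205
tungsten,95,0.0119782
tungsten,100,0.0135473
tungsten,105,0.0152303
tungsten,110,0.0170293
tungsten,115,0.0189465
tungsten,120,0.020984
tungsten,125,0.0231439
tungsten,130,0.0254283
tungsten,135,0.027839
tungsten,140,0.0303781
tungsten,145,0.0330473
tungsten,150,0.0358486
tungsten,155,0.0387837
tungsten,160,0.0418544
tungsten,165,0.0450624
tungsten,170,0.0484095
tungsten,175,0.0518973
tungsten,180,0.0555274
tungsten,185,0.0593015
tungsten,190,0.0632211
tungsten,195,0.0672878
tungsten,200,0.0715032
tungsten,205,0.0758687
tungsten,210,0.0803858
tungsten,215,0.0850561
tungsten,220,0.0898809
tungsten,225,0.0948618
tungsten,230,0.1
tungsten,235,0.105297
tungsten,240,0.110754
tungsten,245,0.116373
tungsten,250,0.122154
lead,10,4.4576e-05
lead,15,0.000118917
lead,20,0.000238558
lead,25,0.00040937
lead,30,0.000636407
lead,35,0.000924157
lead,40,0.00127669
lead,45,0.00169776
lead,50,0.00219083
lead,55,0.00275917
lead,60,0.00340586
lead,65,0.00413382
lead,70,0.00494582
lead,75,0.00584453
lead,80,0.00683249
lead,85,0.00791216
lead,90,0.0090859
lead,95,0.010356
lead,100,0.0117247
lead,105,0.0131941
lead,110,0.0147663
lead,115,0.0164433
lead,120,0.0182272
lead,125,0.0201198
lead,130,0.022123
lead,135,0.0242387
lead,140,0.0264686
lead,145,0.0288146
lead,150,0.0312782
lead,155,0.0338613
lead,160,0.0365655
lead,165,0.0393924
lead,170,0.0423436
lead,175,0.0454207
lead,180,0.0486251
lead,185,0.0519585
lead,190,0.0554224
lead,195,0.0590181
lead,200,0.0627471
lead,205,0.066611
lead,210,0.0706109
lead,215,0.0747485
lead,220,0.0790249
lead,225,0.0834417
lead,230,0.088
lead,235,0.0927012
lead,240,0.0975467
lead,245,0.102538
lead,250,0.107675
brass,10,3.11792e-05
brass,15,8.48809e-05
brass,20,0.000172746
brass,25,0.000299762
brass,30,0.000470278
brass,35,0.000688197
brass,40,0.00095709
brass,45,0.00128026
brass,50,0.00166081
brass,55,0.00210165
brass,60,0.00260554
brass,65,0.00317512
brass,70,0.00381291
brass,75,0.00452133
brass,80,0.0053027
brass,85,0.00615927
brass,90,0.00709323
brass,95,0.00810666
brass,100,0.00920163
brass,105,0.0103801
brass,110,0.0116441
brass,115,0.0129954
brass,120,0.0144359
brass,125,0.0159673
brass,130,0.0175916
brass,135,0.0193103
brass,140,0.0211252
brass,145,0.0230379
brass,150,0.0250501
brass,155,0.0271634
brass,160,0.0293793
brass,165,0.0316993
brass,170,0.0341251
brass,175,0.036658
brass,180,0.0392996
brass,185,0.0420513
brass,190,0.0449145
brass,195,0.0478906
brass,200,0.0509811
brass,205,0.0541872
brass,210,0.0575104
brass,215,0.060952
brass,220,0.0645132
brass,225,0.0681955
brass,230,0.072
brass,235,0.0759281
brass,240,0.0799809
brass,245,0.0841599
brass,250,0.088466
nickel,10,2.74192e-05
nickel,15,7.56198e-05
nickel,20,0.000155322
nickel,25,0.000271457
nickel,30,0.000428363
nickel,35,0.00062996
nickel,40,0.000879851
nickel,45,0.00118139
nickel,50,0.00153772
nickel,55,0.00195183
nickel,60,0.00242655
nickel,65,0.00296459
nickel,70,0.00356854
nickel,75,0.0042409
nickel,80,0.00498409
nickel,85,0.00580044
nickel,90,0.00669221
nickel,95,0.0076616
nickel,100,0.00871074
nickel,105,0.00984171
nickel,110,0.0110565
nickel,115,0.0123572
nickel,120,0.0137457
nickel,125,0.0152238
nickel,130,0.0167935
nickel,135,0.0184565
nickel,140,0.0202147
nickel,145,0.0220698
nickel,150,0.0240234
nickel,155,0.0260774
nickel,160,0.0282334
nickel,165,0.030493
nickel,170,0.0328578
nickel,175,0.0353294
nickel,180,0.0379094
nickel,185,0.0405993
nickel,190,0.0434007
nickel,195,0.046315
nickel,200,0.0493437
nickel,205,0.0524884
nickel,210,0.0557504
nickel,215,0.0591311
nickel,220,0.062632
nickel,225,0.0662545
nickel,230,0.07
nickel,235,0.0738698
nickel,240,0.0778652
nickel,245,0.0819877
nickel,250,0.0862384
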