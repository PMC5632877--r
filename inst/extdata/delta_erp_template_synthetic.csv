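0.000000
0.000002
0.000013
0.000044
0.000105
0.000205
0.000354
0.000562
0.000837
0.001189
0.001627
0.002160
0.002796
0.003544
0.004412
0.005407
0.006537
0.007809
0.009229
0.010804
0.012541
0.014444
0.016518
0.018769
0.021200
0.023815
0.026617
0.029610
0.032795
0.036175
0.039750
0.043521
0.047488
0.051651
0.056009
0.060560
0.065303
0.070234
0.075351
0.080650
0.086126
0.091775
0.097592
0.103569
0.109702
0.115982
0.122403
0.128957
0.135634
0.142425
0.149323
0.156315
0.163392
0.170543
0.177757
0.185022
0.192326
0.199656
0.206999
0.214343
0.221675
0.228979
0.236243
0.243452
0.250591
0.257647
0.264604
0.271447
0.278161
0.284730
0.291141
0.297377
0.303424
0.309265
0.314886
0.320271
0.325406
0.330275
0.334864
0.339158
0.343143
0.346804
0.350128
0.353100
0.355709
0.357940
0.359781
0.361220
0.362244
0.362844
0.363007
0.362724
0.361984
0.360777
0.359096
0.356932
0.354277
0.351125
0.347467
0.343300
0.338617
0.333415
0.327689
0.321436
0.314654
0.307342
0.299497
0.291121
0.282213
0.272776
0.262810
0.252319
0.241306
0.229776
0.217734
0.205185
0.192137
0.178596
0.164571
0.150071
0.135105
0.119683
0.103817
0.087519
0.070801
0.053675
0.036157
0.018260
0.000000
-0.018608
-0.037547
-0.056801
-0.076351
-0.096180
-0.116269
-0.136599
-0.157151
-0.177904
-0.198839
-0.219933
-0.241167
-0.262518
-0.283964
-0.305485
-0.327056
-0.348655
-0.370261
-0.391848
-0.413396
-0.434879
-0.456276
-0.477562
-0.498714
-0.519709
-0.540524
-0.561136
-0.581521
-0.601657
-0.621520
-0.641089
-0.660341
-0.679255
-0.697807
-0.715979
-0.733747
-0.751093
-0.767995
-0.784434
-0.800391
-0.815848
-0.830786
-0.845188
-0.859037
-0.872316
-0.885011
-0.897105
-0.908585
-0.919437
-0.929649
-0.939207
-0.948102
-0.956321
-0.963856
-0.970698
-0.976837
-0.982268
-0.986983
-0.990978
-0.994246
-0.996784
-0.998590
-0.999661
-1.000000
-0.999699
-0.998795
-0.997290
-0.995185
-0.992480
-0.989177
-0.985278
-0.980785
-0.975702
-0.970031
-0.963776
-0.956940
-0.949528
-0.941544
-0.932993
-0.923880
-0.914210
-0.903989
-0.893224
-0.881921
-0.870087
-0.857729
-0.844854
-0.831470
-0.817585
-0.803208
-0.788346
-0.773010
-0.757209
-0.740951
-0.724247
-0.707107
-0.689541
-0.671559
-0.653173
-0.634393
-0.615232
-0.595699
-0.575808
-0.555570
-0.534998
-0.514103
-0.492898
-0.471397
-0.449611
-0.427555
-0.405241
-0.382683
-0.359895
-0.336890
-0.313682
-0.290285
-0.266713
-0.242980
-0.219101
-0.195090
-0.170962
-0.146730
-0.122411
-0.098017
-0.073565
-0.049068
-0.024541
-0.000000
0.024541
0.049068
0.073565
0.098017
0.122411
0.146730
0.170962
0.195090
0.219101
0.242980
0.266713
0.290285
0.313682
0.336890
0.359895
0.382683
0.405241
0.427555
0.449611
0.471397
0.492898
0.514103
0.534998
0.555570
0.575808
0.595699
0.615232
0.634393
0.653173
0.671559
0.689541
0.707107
0.724247
0.740951
0.757209
0.773010
0.788346
0.803208
0.817585
0.831470
0.844854
0.857729
0.870087
0.881921
0.893224
0.903989
0.914210
0.923880
0.932993
0.941544
0.949528
0.956940
0.963776
0.970031
0.975702
0.980785
0.985278
0.989177
0.992480
0.995185
0.997290
0.998795
0.999699
1.000000
0.999699
0.998795
0.997290
0.995185
0.992480
0.989177
0.985278
0.980785
0.975702
0.970031
0.963776
0.956940
0.949528
0.941544
0.932993
0.923880
0.914210
0.903989
0.893224
0.881921
0.870087
0.857729
0.844854
0.831470
0.817585
0.803208
0.788346
0.773010
0.757209
0.740951
0.724247
0.707107
0.689541
0.671559
0.653173
0.634393
0.615232
0.595699
0.575808
0.555570
0.534998
0.514103
0.492898
0.471397
0.449611
0.427555
0.405241
0.382683
0.359895
0.336890
0.313682
0.290285
0.266713
0.242980
0.219101
0.195090
0.170962
0.146730
0.122411
0.098017
0.073565
0.049068
0.024541
0.000000
-0.024541
-0.049068
-0.073565
-0.098017
-0.122411
-0.146730
-0.170962
-0.195090
-0.219101
-0.242980
-0.266713
-0.290285
-0.313682
-0.336890
-0.359895
-0.382683
-0.405241
-0.427555
-0.449611
-0.471397
-0.492898
-0.514103
-0.534998
-0.555570
-0.575808
-0.595699
-0.615232
-0.634393
-0.653173
-0.671559
-0.689541
-0.707107
-0.724247
-0.740951
-0.757209
-0.773010
-0.788346
-0.803208
-0.817585
-0.831470
-0.844854
-0.857729
-0.870087
-0.881921
-0.893224
-0.903989
-0.914210
-0.923880
-0.932993
-0.941544
-0.949528
-0.956940
-0.963776
-0.970031
-0.975702
-0.980785
-0.985278
-0.989177
-0.992480
-0.995185
-0.997290
-0.998795
-0.999699
-1.000000
-0.999699
-0.998795
-0.997290
-0.995185
-0.992480
-0.989177
-0.985278
-0.980785
-0.975702
-0.970031
-0.963776
-0.956940
-0.949528
-0.941544
-0.932993
-0.923880
-0.914210
-0.903989
-0.893224
-0.881921
-0.870087
-0.857729
-0.844854
-0.831470
-0.817585
-0.803208
-0.788346
-0.773010
-0.757209
-0.740951
-0.724247
-0.707107
-0.689541
-0.671559
-0.653173
-0.634393
-0.615232
-0.595699
-0.575808
-0.555570
-0.534998
-0.514103
-0.492898
-0.471397
-0.449611
-0.427555
-0.405241
-0.382683
-0.359895
-0.336890
-0.313682
-0.290285
-0.266713
-0.242980
-0.219101
-0.195090
-0.170962
-0.146730
-0.122411
-0.098017
-0.073565
-0.049068
-0.024541
-0.000000
0.024541
0.049068
0.073565
0.098017
0.122411
0.146730
0.170962
0.195090
0.219101
0.242980
0.266713
0.290285
0.313682
0.336890
0.359895
0.382683
0.405241
0.427555
0.449611
0.471397
0.492898
0.514103
0.534998
0.555570
0.575808
0.595699
0.615232
0.634393
0.653173
0.671559
0.689541
0.707107
0.724247
0.740951
0.757209
0.773010
0.788346
0.803208
0.817585
0.831470
0.844854
0.857729
0.870087
0.881921
0.893224
0.903989
0.914210
0.923880
0.932993
0.941544
0.949528
0.956940
0.963776
0.970031
0.975702
0.980785
0.985278
0.989177
0.992480
0.995185
0.997290
0.998795
0.999699
0.999962
0.999493
0.998289
0.996350
0.993679
0.990279
0.986155
0.981312
0.975755
0.969491
0.962528
0.954874
0.946539
0.937532
0.927864
0.917547
0.906594
0.895016
0.882829
0.870047
0.856684
0.842756
0.828281
0.813275
0.797756
0.781742
0.765251
0.748304
0.730920
0.713119
0.694921
0.676348
0.657421
0.638162
0.618593
0.598735
0.578613
0.558248
0.537663
0.516881
0.495926
0.474820
0.453588
0.432251
0.410835
0.389361
0.367853
0.346335
0.324828
0.303356
0.281941
0.260605
0.239371
0.218260
0.197293
0.176493
0.155878
0.135470
0.115288
0.095352
0.075681
0.056292
0.037205
0.018435
0.000000
-0.018084
-0.035802
-0.053138
-0.070079
-0.086610
-0.102720
-0.118395
-0.133625
-0.148398
-0.162704
-0.176535
-0.189881
-0.202734
-0.215088
-0.226937
-0.238273
-0.249094
-0.259394
-0.269171
-0.278422
-0.287144
-0.295338
-0.303003
-0.310139
-0.316747
-0.322830
-0.328390
-0.333430
-0.337954
-0.341968
-0.345476
-0.348485
-0.351001
-0.353031
-0.354584
-0.355667
-0.356291
-0.356463
-0.356195
-0.355497
-0.354380
-0.352856
-0.350935
-0.348632
-0.345958
-0.342927
-0.339551
-0.335845
-0.331823
-0.327498
-0.322885
-0.317999
-0.312855
-0.307467
-0.301851
-0.296021
-0.289994
-0.283783
-0.277404
-0.270873
-0.264205
-0.257414
-0.250516
-0.243525
-0.236457
-0.229325
-0.222144
-0.214928
-0.207690
-0.200446
-0.193206
-0.185986
-0.178796
-0.171650
-0.164559
-0.157535
-0.150589
-0.143731
-0.136972
-0.130321
-0.123787
-0.117380
-0.111108
-0.104978
-0.098998
-0.093174
-0.087513
-0.082020
-0.076700
-0.071558
-0.066598
-0.061824
-0.057238
-0.052842
-0.048639
-0.044629
-0.040814
-0.037193
-0.033766
-0.030532
-0.027490
-0.024637
-0.021972
-0.019490
-0.017189
-0.015065
-0.013113
-0.011328
-0.009705
-0.008239
-0.006922
-0.005749
-0.004713
-0.003806
-0.003021
-0.002351
-0.001786
-0.001318
-0.000940
-0.000641
-0.000413
-0.000246
-0.000131
-0.000059
-0.000020
-0.000003
0.000000
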