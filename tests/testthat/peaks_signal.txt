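0.895108847362
0.784925896806
0.791608519317
0.940521324379
0.885831711207
0.816753371965
0.837986317818
0.908100191542
1.018767534626
0.965901172455
1.072833920515
1.143407208499
0.845137231517
0.848980649018
0.706675333465
0.508966467913
0.264675129474
0.226841198354
0.189399149828
0.222789836638
0.162950713545
0.291537780507
0.062744008309
0.214136213193
0.352029190346
0.569256304101
0.425362455831
0.513106145321
0.374241319001
0.266953727218
0.405601456998
0.595515349830
0.651756593263
0.755411128017
0.677976748156
0.835580505481
0.900937996512
1.016749202325
0.970502692659
0.861085093436
1.101791548666
0.933500107201
0.930721531717
1.008827582655
0.949964422152
1.159959133607
1.237567793366
1.240430784956
1.240250340333
1.153346580547
1.304275753078
1.284667706320
1.264015334559
1.409428440664
1.346995779032
1.187226672022
1.343051951188
1.283293750598
1.233358064771
1.122423353382
0.982177590749
0.967768851565
0.993492886150
0.960903932350
0.888918872186
0.778054319255
0.901411096934
0.665890186334
0.746337371100
0.799894556748
0.961362440092
0.938100221033
0.774496284624
0.880602051112
0.941096158386
1.038499044817
1.212320693884
1.230041746838
1.280027968278
1.126940699125
1.028419795955
0.940991604518
0.980664318525
0.959177004919
0.919465713333
1.039589429475
1.070649071181
1.105737066290
1.081392721110
1.220216119598
1.343401406540
1.409501831231
1.315356050970
1.224306303491
0.964162679039
0.740697642158
0.632602319827
0.570373646950
0.471698806649
0.721716160777
0.564482212378
0.638587730032
0.622890385274
0.865247875139
1.071794861698
1.082744478082
1.260787873940
1.300327300754
0.936057027580
1.019672790113
1.092920616236
0.952932997557
0.927024754141
0.851296930667
0.982185490464
0.925550263517
0.877705691155
0.926888744401
0.922507799372
0.696615228087
0.688068244923
0.699512766980
0.558333815353
0.544394016860
0.328967084862
0.403126197850
0.374851900070
0.474585334317
0.711107278816
0.666059782175
0.764538554438
1.161235687477
1.059856417756
1.223431995890
1.121586943819
1.107180800497
1.142691431099
1.067819971175
1.232891585353
1.005953235046
0.776199873352
0.641542068280
0.811651577823
0.812293732574
1.027968614964
0.907383930204
0.890549308429
0.859938769839
0.885834920139
0.956282942240
1.056556088014
0.883557084719
0.747502961283
0.550528789466
0.732832450787
0.735406929837
0.654583760101
0.754312358221
0.909791591596
0.789929651284
0.800085192139
0.883032095494
0.777012812527
0.674887163689
0.746863752322
0.871923266979
0.750852399755
0.645020395692
0.746656723803
0.753947683776
0.701035657304
0.761581958873
0.828315863988
0.774575776657
0.799046722442
0.878882393295
0.779334685988
0.782816505894
0.868703816998
0.958303060070
1.076598516963
0.930675150507
1.117743264373
1.160946666404
1.207212300014
1.193609389949
1.096497417763
1.131991566684
1.272915426546
1.274108231996
1.331848485819
1.287952345111
1.304693842671
1.364558643284
1.376553503583
1.698435914991
1.454422249433
1.442786243074
1.513301851758
1.550161326416
1.672113021217
1.744697579074
1.515079759026
1.378073766847
1.300508886446
1.326240068936
1.229114683865
1.267536394751
0.987823454228
0.544602480738
0.408475097067
0.540648741156
0.700967464365
0.614483653778
0.631649965835
0.464862297099
0.353042038445
0.427718556238
0.479551793115
0.506927576566
0.495173741229
0.567655031008
0.453451730431
0.475946932156
0.533108196607
0.453109639254
0.582789262453
0.678401118684
0.661777253954
0.706349982158
0.886198032186
0.841365353915
1.013138817211
1.114200491137
1.211157395240
1.028349424167
1.064213957902
1.107228510638
1.060313588700
0.844301742426
0.966754227456
0.996383935139
1.003941201233
0.761009429861
0.845208460020
0.677585927314
0.233737518543
0.184000076570
0.323167352091
0.360704750617
0.102136366795
0.000000000000
0.370114322526
0.464525341845
0.688613769472
1.043944505767
1.107112907026
1.048429106675
1.104589927922
1.258839973192
1.247487918816
1.178654089334
1.085112566957
1.201317726328
1.066030056007
1.046472140692
0.956165037000
0.747585831666
0.914948825425
1.193090505964
1.084791336351
1.246565585635
1.167102296054
1.017934669207
1.061047890602
1.055049469097
1.211478680666
0.900495729146
0.708300860981
0.740003638562
0.786267310967
0.781350754381
1.071129024730
1.213192578245
1.158314372697
1.105797966214
1.023589067157
1.227861610768
1.354816180943
1.324677717310
1.361841204650
1.374697162190
1.228754822332
1.262448304498
1.283096068848
1.490991471410
1.484627434218
1.439222493509
1.330854919034
1.192155974935
1.109361855483
1.263496974593
1.347796296203
1.377924183318
1.333425799555
1.042216585859
0.973044423717
1.076613108187
1.097374753032
1.142680964633
0.940043257676
0.895921820318
0.711414993978
0.723724270666
0.752019592171
0.857735879952
0.675040689837
0.782772244741
0.977403359822
0.967118703173
0.888099745382
1.086371205145
1.112301130074
1.096832149053
1.049758191625
1.359326494963
1.266531079122
1.074607340368
0.993347811225
1.095643889426
0.935820724555
0.813053836029
1.065640904827
0.913821740926
0.810026353799
1.008078575915
1.059434426309
1.237025918133
1.418488417244
1.535182619760
1.592285422806
1.299741163180
1.404981178707
1.449179694439
1.386428291952
1.252937436519
1.096407793555
0.823471996551
0.877804939281
0.920882091485
1.095069314843
1.123406236810
0.925859814855
0.814774334521
0.942405847702
1.028117589958
1.140083378217
1.315484232754
1.404071311851
1.386444267514
1.166126711802
1.242430119879
1.030596289861
0.851082238375
0.955372122376
0.977895921836
0.753360947205
0.497585014880
0.450122896736
0.562054041752
0.589707781765
1.056864331120
1.237527061577
1.055977019299
0.847445175917
0.857872366759
1.028229912608
0.941544285648
1.029888013860
0.831248650811
0.703957177400
0.797926079382
1.005044123085
1.082433129717
1.145834779060
1.150804077760
1.235549310885
1.184938100570
1.168404572601
0.884407798420
0.854592707874
0.712816411295
0.789535891488
0.843668094281
0.665772206525
0.621847982924
0.659530833717
0.803943641832
0.964372941376
0.876115742390
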