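r_cm,theta_deg,F
0.25,0,0.8985
0.25,10,0.9015
0.25,20,0.9103
0.25,30,0.9239
0.25,40,0.9404
0.25,50,0.958
0.25,60,0.9746
0.25,70,0.9881
0.25,80,0.9969
0.25,90,1
0.25,100,0.9969
0.25,110,0.9881
0.25,120,0.9746
0.25,130,0.958
0.25,140,0.9404
0.25,150,0.9239
0.25,160,0.9103
0.25,170,0.9015
0.25,180,0.8985
0.5,0,0.9018
0.5,10,0.9048
0.5,20,0.9133
0.5,30,0.9263
0.5,40,0.9424
0.5,50,0.9594
0.5,60,0.9754
0.5,70,0.9885
0.5,80,0.997
0.5,90,1
0.5,100,0.997
0.5,110,0.9885
0.5,120,0.9754
0.5,130,0.9594
0.5,140,0.9424
0.5,150,0.9263
0.5,160,0.9133
0.5,170,0.9048
0.5,180,0.9018
1,0,0.908
1,10,0.9108
1,20,0.9188
1,30,0.931
1,40,0.946
1,50,0.962
1,60,0.977
1,70,0.9892
1,80,0.9972
1,90,1
1,100,0.9972
1,110,0.9892
1,120,0.977
1,130,0.962
1,140,0.946
1,150,0.931
1,160,0.9188
1,170,0.9108
1,180,0.908
2,0,0.9191
2,10,0.9215
2,20,0.9286
2,30,0.9393
2,40,0.9525
2,50,0.9666
2,60,0.9798
2,70,0.9905
2,80,0.9976
2,90,1
2,100,0.9976
2,110,0.9905
2,120,0.9798
2,130,0.9666
2,140,0.9525
2,150,0.9393
2,160,0.9286
2,170,0.9215
2,180,0.9191
3,0,0.9284
3,10,0.9306
3,20,0.9368
3,30,0.9463
3,40,0.958
3,50,0.9704
3,60,0.9821
3,70,0.9916
3,80,0.9978
3,90,1
3,100,0.9978
3,110,0.9916
3,120,0.9821
3,130,0.9704
3,140,0.958
3,150,0.9463
3,160,0.9368
3,170,0.9306
3,180,0.9284
5,0,0.9431
5,10,0.9448
5,20,0.9497
5,30,0.9573
5,40,0.9666
5,50,0.9765
5,60,0.9858
5,70,0.9933
5,80,0.9983
5,90,1
5,100,0.9983
5,110,0.9933
5,120,0.9858
5,130,0.9765
5,140,0.9666
5,150,0.9573
5,160,0.9497
5,170,0.9448
5,180,0.9431
8,0,0.9576
8,10,0.9589
8,20,0.9626
8,30,0.9682
8,40,0.9751
8,50,0.9825
8,60,0.9894
8,70,0.995
8,80,0.9987
8,90,1
8,100,0.9987
8,110,0.995
8,120,0.9894
8,130,0.9825
8,140,0.9751
8,150,0.9682
8,160,0.9626
8,170,0.9589
8,180,0.9576
12,0,0.9685
12,10,0.9694
12,20,0.9722
12,30,0.9764
12,40,0.9815
12,50,0.987
12,60,0.9921
12,70,0.9963
12,80,0.9991
12,90,1
12,100,0.9991
12,110,0.9963
12,120,0.9921
12,130,0.987
12,140,0.9815
12,150,0.9764
12,160,0.9722
12,170,0.9694
12,180,0.9685
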