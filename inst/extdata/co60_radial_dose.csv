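r_cm,g
0.1,0.988
0.25,0.99
0.5,0.995
0.75,0.998
1,1
1.5,1.001
2,1
2.5,0.998
3,0.995
4,0.988
5,0.978
6,0.966
7,0.952
8,0.937
10,0.903
12,0.865
15,0.804
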