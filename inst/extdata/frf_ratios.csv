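"tone","ratio1","ratio2"
1,1,0
2,0.976,0
3,0.932,0.002
4,0.875,0.006
5,0.808,0.022
6,0.731,0.059
7,0.646,0.129
8,0.554,0.224
9,0.456,0.313
10,0.35,0.35
11,0.239,0.313
12,0.122,0.224
13,0,0.129
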