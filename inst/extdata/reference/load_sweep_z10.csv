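F_N,x_mm,k
0.1,0.4233,0.236239
0.2,0.8466,0.236239
0.3,1.2699,0.236239
0.4,1.6932,0.236239
0.5,2.1165,0.236239
0.8,3.3864,0.236239
0.9,3.8097,0.236239
1,4.233,0.236239
2,8.466,0.236239
5,21.165,0.236239
10,42.33,0.236239
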