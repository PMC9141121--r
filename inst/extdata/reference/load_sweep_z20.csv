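F_N,x_mm,k
0.1,2.1089,0.047418
0.2,4.2178,0.047418
0.3,6.3267,0.047418
0.4,8.4356,0.047418
0.5,10.5445,0.047418
0.6,12.6534,0.047418
0.7,14.7623,0.047418
0.8,16.8712,0.047418
0.9,18.9801,0.047418
1,21.089,0.047418
2,42.178,0.047418
3,63.267,0.047418
4,84.356,0.047418
5,105.445,0.047418
10,210.89,0.047418
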