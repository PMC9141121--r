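F_N,x_mm,k
0.1,0.96311,0.10383
0.2,1.92622,0.10383
0.3,2.88933,0.10383
0.4,3.85244,0.10383
0.5,4.8156,0.103829
0.6,5.77872,0.103829
0.7,6.74184,0.103829
0.8,7.70496,0.103829
0.9,8.66808,0.103829
1,9.6311,0.10383
2,19.2622,0.10383
3,28.8933,0.10383
4,38.5244,0.10383
5,48.1555,0.10383
10,96.311,0.10383
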