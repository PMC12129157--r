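no,diagnosis,mmse,label,probability
1,SCD,30,0,0.0367
2,SCD,29,0,0.2156
3,SCD,29,0,0.1927
4,SCD,28,0,0.2509
5,SCD,28,0,0.2191
6,MCI,27,0,0.2174
7,MCI,26,0,0.2940
8,MCI,25,0,0.2372
9,MCI,25,0,0.1882
10,MCI,25,0,0.3585
11,MCI,24,0,0.4930
12,MCI,24,0,0.3877
13,AD,23,1,0.4734
14,AD,23,1,0.5320
15,AD,21,1,0.7185
16,DLB,19,1,0.7641
17,AD,18,1,0.5831
18,VaD,17,1,0.7356
19,AD,13,1,0.7136
20,DLB,13,1,0.8704
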