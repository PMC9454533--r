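patient_id,plasma_ng_ml,urine_ng_ml
1,37,206
2,218,160
3,80,180
4,356,412
5,252,0
6,172,1820
7,244,196
8,420,0
9,69,650
10,212,192
11,118,1730
12,442,1410
13,112,180
14,158,110
15,80,254
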