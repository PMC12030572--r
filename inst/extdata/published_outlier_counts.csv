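duration_h,CK,ND,PD,KD
24,37,9,4,1
72,2,3,0,0
120,1,2,1,1
168,1,0,0,1
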