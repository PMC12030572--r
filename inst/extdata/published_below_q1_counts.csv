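duration_h,CK,ND,PD,KD
24,107,35,23,6
72,22,28,19,7
120,21,23,11,6
168,15,11,4,4
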