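position,n10,n20,n30
P1,0.99211,0.99139,0.99135
P2,0.99191,0.99153,0.99134
P3,0.99273,0.99215,0.99203
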