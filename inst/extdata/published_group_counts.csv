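group,n_spectra
CK,420
ND,303
PD,307
KD,337
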