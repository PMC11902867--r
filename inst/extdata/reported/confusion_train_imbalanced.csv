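"",H1,H2,H3,H4
H1,5,2,6,2
H2,4,17,8,11
H3,0,2,85,15
H4,0,3,21,156
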