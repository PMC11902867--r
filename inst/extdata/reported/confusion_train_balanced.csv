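"",H1,H2,H3,H4
H1,12,2,1,0
H2,1,14,0,0
H3,0,2,12,1
H4,0,1,1,13
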