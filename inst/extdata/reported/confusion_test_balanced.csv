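"",H1,H2,H3,H4
H1,4,1,1,0
H2,1,5,0,0
H3,0,0,6,0
H4,1,1,0,4
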