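"",H1,H2,H3,H4
H1,2,1,1,2
H2,1,1,5,3
H3,0,2,32,10
H4,0,1,12,59
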