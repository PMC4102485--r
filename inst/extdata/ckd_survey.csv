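a,b,c,ab,ac,bc,abc
0.25,0.01,0.11,0.10,0.29,0.03,0.15
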