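ph,f
3,0.05
4,0.15
5,0.45
6,0.75
7,1
9,1
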