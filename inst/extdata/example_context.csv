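object,a,b,c,d
1,1,0,0,0
2,1,1,0,0
3,1,1,0,0
4,1,1,0,1
5,1,1,1,0
6,1,0,1,0
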