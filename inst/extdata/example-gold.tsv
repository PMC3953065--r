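ex1	1,3,3
nx1	2,1
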