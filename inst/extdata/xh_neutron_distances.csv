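element,d_xh
C,1.089
N,1.015
O,0.993
B,1.185
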