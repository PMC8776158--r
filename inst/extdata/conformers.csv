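system,conformer,residue_count,structure_label
Fa,A,1,beta_L(a)
Fa,B,1,gamma_L(g+)
Fa,C,1,gamma_L(g-)
Fa,D,1,gamma_L(a)
GFa,A,2,7_L-7_L(g-)
GFa,B',2,pi-10II'(g+)
FFa,A1,2,pi-pi-10I(g+;g+)
FFa,A2,2,pi-pi-10I(g+;g+)
FFa,C,2,5-pi-7_L(a;g+)
QFa,A,2,7eps-pi-10I(g+)
QFa,C,2,7eps-pi-10I(g+)
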