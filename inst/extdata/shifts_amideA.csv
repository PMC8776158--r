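system,conformer,method,site_label,mode_class,harmonic_cm1,corrected_cm1,coupled,experimental_cm1
Fa,A,CC2,NH_Phe,NH,11,9,false,-1
Fa,A,CC2,NH2_sym,NH2sym,-15,-10,false,-9
Fa,A,CC2,NH2_anti,NH2anti,-18,-9,false,-6
Fa,B,CC2,NH_Phe,NH,-44,-37,false,
Fa,B,CC2,NH2_sym,NH2sym,-5,-4,false,
Fa,B,CC2,NH2_anti,NH2anti,-1,-1,false,
Fa,C,CC2,NH_Phe,NH,-44,-37,false,-24
Fa,C,CC2,NH2_sym,NH2sym,-3,-1,false,-1
Fa,C,CC2,NH2_anti,NH2anti,-1,-1,false,-1
Fa,D,CC2,NH_Phe,NH,0,0,false,
Fa,D,CC2,NH2_sym,NH2sym,-2,-2,false,
Fa,D,CC2,NH2_anti,NH2anti,0,,false,
Fa,A,CAM-B3LYP,NH_Phe,NH,-6,,false,-1
Fa,A,CAM-B3LYP,NH2_sym,NH2sym,-29,,false,-9
Fa,A,CAM-B3LYP,NH2_anti,NH2anti,-22,,false,-6
Fa,B,CAM-B3LYP,NH_Phe,NH,-44,,false,
Fa,B,CAM-B3LYP,NH2_sym,NH2sym,-5,,false,
Fa,B,CAM-B3LYP,NH2_anti,NH2anti,-2,,false,
Fa,C,CAM-B3LYP,NH_Phe,NH,-38,,false,-24
Fa,C,CAM-B3LYP,NH2_sym,NH2sym,-8,,false,-1
Fa,C,CAM-B3LYP,NH2_anti,NH2anti,-1,,false,-1
Fa,D,CAM-B3LYP,NH_Phe,NH,-1,,false,
Fa,D,CAM-B3LYP,NH2_sym,NH2sym,0,,false,
Fa,D,CAM-B3LYP,NH2_anti,NH2anti,9,,false,
Fa,A,wB97X-D,NH_Phe,NH,10,,false,-1
Fa,A,wB97X-D,NH2_sym,NH2sym,-9,,false,-9
Fa,A,wB97X-D,NH2_anti,NH2anti,-8,,false,-6
Fa,B,wB97X-D,NH_Phe,NH,-25,,false,
Fa,B,wB97X-D,NH2_sym,NH2sym,-6,,false,
Fa,B,wB97X-D,NH2_anti,NH2anti,-3,,false,
Fa,C,wB97X-D,NH_Phe,NH,-44,,false,-24
Fa,C,wB97X-D,NH2_sym,NH2sym,-2,,false,-1
Fa,C,wB97X-D,NH2_anti,NH2anti,2,,false,-1
Fa,D,wB97X-D,NH_Phe,NH,-1,,false,
Fa,D,wB97X-D,NH2_sym,NH2sym,-7,,false,
Fa,D,wB97X-D,NH2_anti,NH2anti,-1,,false,
GFa,A,CC2,NH_Gly,NH,-7,-6,false,-2
GFa,A,CC2,NH_Phe,NH,-18,-15,false,-18
GFa,A,CC2,NH2_sym,NH2sym,-5,-3,false,3
GFa,A,CC2,NH2_anti,NH2anti,0,0,false,-9
GFa,B',CC2,NH_Gly,NH,0,0,false,1
GFa,B',CC2,NH_Phe,NH,-21,-18,false,-18
GFa,B',CC2,NH2_sym,NH2sym,1,1,false,2
GFa,B',CC2,NH2_anti,NH2anti,0,0,false,1
FFa,A1,CC2,NH_Phe1,NH,-41,-35,false,-33
FFa,A1,CC2,NH_Phe2,NH,-9,-8,false,0
FFa,A1,CC2,NH2_sym,NH2sym,-4,-3,false,-1
FFa,A1,CC2,NH2_anti,NH2anti,-2,-1,false,0
FFa,A2,CC2,NH_Phe1,NH,-5,-4,false,-1
FFa,A2,CC2,NH_Phe2,NH,-34,-29,false,-24
FFa,A2,CC2,NH2_sym,NH2sym,-2,-1,false,-1
FFa,A2,CC2,NH2_anti,NH2anti,-1,-1,false,0
FFa,C,CC2,NH_Phe1,NH,-12,-10,false,
FFa,C,CC2,NH_Phe2,NH,-74,-63,false,
FFa,C,CC2,NH2_sym,NH2sym,-30,-21,false,
FFa,C,CC2,NH2_anti,NH2anti,-11,-6,false,
QFa,A,CC2,NH_Gln,NH,-2,-2,false,
QFa,A,CC2,NH_Phe,NH,-12,-10,false,
QFa,A,CC2,NH2_sym/C-term,NH2sym,5,3,false,
QFa,A,CC2,NH2_anti/C-term,NH2anti,8,4,false,
QFa,A,CC2,NH2_sym/Chain,NH2sym,-2,-1,false,
QFa,A,CC2,NH2_anti/Chain,NH2anti,-2,-1,false,
QFa,C,CC2,NH_Gln,NH,-9,-8,false,
QFa,C,CC2,NH_Phe,NH,-16,-14,false,
QFa,C,CC2,NH2_sym/C-term,NH2sym,-2,-1,false,
QFa,C,CC2,NH2_anti/C-term,NH2anti,0,0,false,
QFa,C,CC2,NH2_sym/Chain,NH2sym,-1,-1,false,
QFa,C,CC2,NH2_anti/Chain,NH2anti,1,1,false,
GFa,A,wB97X-D,NH_Gly,NH,-2,-2,false,-2
GFa,A,wB97X-D,NH_Phe,NH,-10,-9,true,-18
GFa,A,wB97X-D,NH2_sym,NH2sym,3,2,true,3
GFa,A,wB97X-D,NH2_anti,NH2anti,1,1,false,-9
GFa,B',wB97X-D,NH_Gly,NH,-1,-1,false,1
GFa,B',wB97X-D,NH_Phe,NH,-4,-4,false,-18
GFa,B',wB97X-D,NH2_sym,NH2sym,1,1,false,2
GFa,B',wB97X-D,NH2_anti,NH2anti,1,1,false,1
FFa,A1,wB97X-D,NH_Phe1,NH,-40,-36,false,-33
FFa,A1,wB97X-D,NH_Phe2,NH,-7,-6,false,0
FFa,A1,wB97X-D,NH2_sym,NH2sym,3,2,false,-1
FFa,A1,wB97X-D,NH2_anti,NH2anti,0,0,false,0
FFa,A2,wB97X-D,NH_Phe1,NH,-6,-5,true,-1
FFa,A2,wB97X-D,NH_Phe2,NH,-21,-19,true,-24
FFa,A2,wB97X-D,NH2_sym,NH2sym,3,2,false,-1
FFa,A2,wB97X-D,NH2_anti,NH2anti,0,0,false,0
FFa,C,wB97X-D,NH_Phe1,NH,-9,-8,false,
FFa,C,wB97X-D,NH_Phe2,NH,-60,-55,true,
FFa,C,wB97X-D,NH2_sym,NH2sym,-21,-15,true,
FFa,C,wB97X-D,NH2_anti,NH2anti,-7,-6,false,
QFa,A,wB97X-D,NH_Gln,NH,-6,-5,false,
QFa,A,wB97X-D,NH_Phe,NH,-22,-20,false,
QFa,A,wB97X-D,NH2_sym/C-term,NH2sym,-2,-1,false,
QFa,A,wB97X-D,NH2_anti/C-term,NH2anti,0,0,false,
QFa,A,wB97X-D,NH2_sym/Chain,NH2sym,0,0,false,
QFa,A,wB97X-D,NH2_anti/Chain,NH2anti,0,0,false,
QFa,C,wB97X-D,NH_Gln,NH,-9,-8,false,
QFa,C,wB97X-D,NH_Phe,NH,-32,-29,false,
QFa,C,wB97X-D,NH2_sym/C-term,NH2sym,-2,-1,false,
QFa,C,wB97X-D,NH2_anti/C-term,NH2anti,0,0,false,
QFa,C,wB97X-D,NH2_sym/Chain,NH2sym,-2,-1,false,
QFa,C,wB97X-D,NH2_anti/Chain,NH2anti,3,2,false,
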