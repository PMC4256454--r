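resname,code,bb_type,sc_types,sc_charges,sc_bond_length,sc_bond_k
ALA,A,P4,,,0.31,7500
ARG,R,P5,N0;Qd,0;1,0.33,7500
ASN,N,P5,P5,0,0.32,7500
ASP,D,P5,Qa,-1,0.32,7500
CYS,C,P5,C5,0,0.31,7500
GLN,Q,P5,P4,0,0.40,7500
GLU,E,P5,Qa,-1,0.40,7500
GLY,G,P5,,,0.31,7500
HIS,H,P5,SC4;SP1;SP1,0;0;0,0.32,7500
ILE,I,P5,C1,0,0.31,7500
LEU,L,P5,C1,0,0.33,7500
LYS,K,P5,C3;Qd,0;1,0.33,7500
MET,M,P5,C5,0,0.40,7500
PHE,F,P5,SC5;SC5;SC5,0;0;0,0.31,7500
PRO,P,P4,C2,0,0.30,7500
SER,S,P5,P1,0,0.25,7500
THR,T,P5,P1,0,0.26,7500
TRP,W,P5,SC4;SNd;SC5;SC5,0;0;0;0,0.30,7500
TYR,Y,P5,SC4;SC4;SP1,0;0;0,0.32,7500
VAL,V,P5,C2,0,0.27,7500
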