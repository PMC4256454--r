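type_a,type_b,epsilon,sigma
P5,P5,5,0.47
P5,P4,5,0.47
P5,P1,5,0.47
P5,SP1,5,0.47
P5,Q0,5.6,0.47
P5,Qa,5.6,0.47
P5,Qd,5.6,0.47
P5,N0,4.5,0.47
P5,Na,4.5,0.47
P5,SNd,4.5,0.47
P5,C1,2.3,0.47
P5,C2,2.3,0.47
P5,C3,2.3,0.47
P5,C5,2.3,0.47
P5,SC1,2.3,0.47
P5,SC4,2.3,0.47
P5,SC5,2.3,0.47
P4,P4,5,0.47
P4,P1,5,0.47
P4,SP1,5,0.47
P4,Q0,5.6,0.47
P4,Qa,5.6,0.47
P4,Qd,5.6,0.47
P4,N0,4.5,0.47
P4,Na,4.5,0.47
P4,SNd,4.5,0.47
P4,C1,2.3,0.47
P4,C2,2.3,0.47
P4,C3,2.3,0.47
P4,C5,2.3,0.47
P4,SC1,2.3,0.47
P4,SC4,2.3,0.47
P4,SC5,2.3,0.47
P1,P1,5,0.47
P1,SP1,5,0.47
P1,Q0,5.6,0.47
P1,Qa,5.6,0.47
P1,Qd,5.6,0.47
P1,N0,4.5,0.47
P1,Na,4.5,0.47
P1,SNd,4.5,0.47
P1,C1,2.3,0.47
P1,C2,2.3,0.47
P1,C3,2.3,0.47
P1,C5,2.3,0.47
P1,SC1,2.3,0.47
P1,SC4,2.3,0.47
P1,SC5,2.3,0.47
SP1,SP1,3.75,0.43
SP1,Q0,5.6,0.47
SP1,Qa,5.6,0.47
SP1,Qd,5.6,0.47
SP1,N0,4.5,0.47
SP1,Na,4.5,0.47
SP1,SNd,3.375,0.43
SP1,C1,2.3,0.47
SP1,C2,2.3,0.47
SP1,C3,2.3,0.47
SP1,C5,2.3,0.47
SP1,SC1,1.725,0.43
SP1,SC4,1.725,0.43
SP1,SC5,1.725,0.43
Q0,Q0,4.5,0.47
Q0,Qa,4.5,0.47
Q0,Qd,4.5,0.47
Q0,N0,4.5,0.47
Q0,Na,4.5,0.47
Q0,SNd,4.5,0.47
Q0,C1,2,0.47
Q0,C2,2,0.47
Q0,C3,2,0.47
Q0,C5,2,0.47
Q0,SC1,2,0.47
Q0,SC4,2,0.47
Q0,SC5,2,0.47
Qa,Qa,4.5,0.47
Qa,Qd,4.5,0.47
Qa,N0,4.5,0.47
Qa,Na,4.5,0.47
Qa,SNd,4.5,0.47
Qa,C1,2,0.47
Qa,C2,2,0.47
Qa,C3,2,0.47
Qa,C5,2,0.47
Qa,SC1,2,0.47
Qa,SC4,2,0.47
Qa,SC5,2,0.47
Qd,Qd,4.5,0.47
Qd,N0,4.5,0.47
Qd,Na,4.5,0.47
Qd,SNd,4.5,0.47
Qd,C1,2,0.47
Qd,C2,2,0.47
Qd,C3,2,0.47
Qd,C5,2,0.47
Qd,SC1,2,0.47
Qd,SC4,2,0.47
Qd,SC5,2,0.47
N0,N0,4.5,0.47
N0,Na,4.5,0.47
N0,SNd,4.5,0.47
N0,C1,2.7,0.47
N0,C2,2.7,0.47
N0,C3,2.7,0.47
N0,C5,2.7,0.47
N0,SC1,2.7,0.47
N0,SC4,2.7,0.47
N0,SC5,2.7,0.47
Na,Na,4.5,0.47
Na,SNd,4.5,0.47
Na,C1,2.7,0.47
Na,C2,2.7,0.47
Na,C3,2.7,0.47
Na,C5,2.7,0.47
Na,SC1,2.7,0.47
Na,SC4,2.7,0.47
Na,SC5,2.7,0.47
SNd,SNd,3.375,0.43
SNd,C1,2.7,0.47
SNd,C2,2.7,0.47
SNd,C3,2.7,0.47
SNd,C5,2.7,0.47
SNd,SC1,2.025,0.43
SNd,SC4,2.025,0.43
SNd,SC5,2.025,0.43
C1,C1,3.5,0.47
C1,C2,3.5,0.47
C1,C3,3.5,0.47
C1,C5,3.5,0.47
C1,SC1,3.5,0.47
C1,SC4,3.5,0.47
C1,SC5,3.5,0.47
C2,C2,3.5,0.47
C2,C3,3.5,0.47
C2,C5,3.5,0.47
C2,SC1,3.5,0.47
C2,SC4,3.5,0.47
C2,SC5,3.5,0.47
C3,C3,3.5,0.47
C3,C5,3.5,0.47
C3,SC1,3.5,0.47
C3,SC4,3.5,0.47
C3,SC5,3.5,0.47
C5,C5,3.5,0.47
C5,SC1,3.5,0.47
C5,SC4,3.5,0.47
C5,SC5,3.5,0.47
SC1,SC1,2.625,0.43
SC1,SC4,2.625,0.43
SC1,SC5,2.625,0.43
SC4,SC4,2.625,0.43
SC4,SC5,2.625,0.43
SC5,SC5,2.625,0.43
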