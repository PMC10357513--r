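left,right
Fp1,Fp2
F7,F8
F3,F4
FT7,FT8
FC3,FC4
T7,T8
P7,P8
C3,C4
TP7,TP8
CP3,CP4
P3,P4
O1,O2
AF3,AF4
F5,F6
FC5,FC6
FC1,FC2
C5,C6
C1,C2
CP5,CP6
CP1,CP2
AF7,AF8
P5,P6
P1,P2
PO7,PO8
PO3,PO4
FT9,FT10
TP9,TP10
F1,F2
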