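frontal,posterior
FT7,TP7
FC5,CP5
FC3,CP3
FC1,CP1
FCz,CPz
FC2,CP2
FC4,CP4
FC6,CP6
FT8,TP8
F7,P7
F5,P5
F3,P3
F1,P1
Fz,Pz
F2,P2
F4,P4
F6,P6
F8,P8
Fp1,O1
Fp2,O2
AF3,CB1
AF4,CB2
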