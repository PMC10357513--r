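label,role,x,y
Fp1,data,-0.309017,0.951057
Fp2,data,0.309017,0.951057
AF7,data,-0.587785,0.809017
AF3,data,-0.27039,0.832174
AF4,data,0.27039,0.832174
AF8,data,0.587785,0.809017
F7,data,-0.809017,0.587785
F5,data,-0.568267,0.665355
F3,data,-0.340493,0.668255
F1,data,-0.145903,0.607731
Fz,data,0,0.5
F2,data,0.145903,0.607731
F4,data,0.340493,0.668255
F6,data,0.568267,0.665355
F8,data,0.809017,0.587785
FT9,data,-1.093715,0.35537
FT7,data,-0.951057,0.309017
FC5,data,-0.657326,0.477576
FC3,data,-0.367366,0.505636
FC1,data,-0.135195,0.416087
FC2,data,0.135195,0.416087
FC4,data,0.367366,0.505636
FC6,data,0.657326,0.477576
FT8,data,0.951057,0.309017
FT10,data,1.093715,0.35537
T7,data,-1,0
C5,data,-0.75,0
C3,data,-0.5,0
C1,data,-0.25,0
Cz,data,0,0
C2,data,0.25,0
C4,data,0.5,0
C6,data,0.75,0
T8,data,1,0
TP9,data,-1.093715,-0.35537
TP7,data,-0.951057,-0.309017
CP5,data,-0.657326,-0.477576
CP3,data,-0.367366,-0.505636
CP1,data,-0.135195,-0.416087
CPz,data,0,-0.25
CP2,data,0.135195,-0.416087
CP4,data,0.367366,-0.505636
CP6,data,0.657326,-0.477576
TP8,data,0.951057,-0.309017
TP10,data,1.093715,-0.35537
P7,data,-0.809017,-0.587785
P5,data,-0.568267,-0.665355
P3,data,-0.340493,-0.668255
P1,data,-0.145903,-0.607731
Pz,data,0,-0.5
P2,data,0.145903,-0.607731
P4,data,0.340493,-0.668255
P6,data,0.568267,-0.665355
P8,data,0.809017,-0.587785
PO7,data,-0.587785,-0.809017
PO3,data,-0.27039,-0.832174
PO4,data,0.27039,-0.832174
PO8,data,0.587785,-0.809017
O1,data,-0.309017,-0.951057
Oz,data,0,-1
O2,data,0.309017,-0.951057
CB1,data,-0.575,-0.995929
CB2,data,0.575,-0.995929
FCz,reference,0,0.25
Fpz,ground,0,1
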