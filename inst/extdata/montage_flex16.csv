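label,role,alternate_for
Fp1,standard,
Fp2,standard,
F3,standard,
F4,standard,
F7,standard,
F8,standard,
C3,standard,
C4,standard,
T7,standard,
T8,standard,
P3,standard,
P4,standard,
P7,standard,
P8,standard,
O1,standard,
O2,standard,
AF3,alternate,Fp1
AF4,alternate,Fp2
FC1,alternate,F3
FC2,alternate,F4
FC5,alternate,F7
FC6,alternate,F8
Cz,alternate,C3
Fz,alternate,C4
CP5,alternate,T7
CP6,alternate,T8
CP1,alternate,P3
CP2,alternate,P4
PO3,alternate,P7
PO4,alternate,P8
Oz,alternate,O1
Pz,alternate,O2
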