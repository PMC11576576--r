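symbol,Z,A,I_eV
H,1,1.008,19.2
C,6,12.011,78
N,7,14.007,82
O,8,15.999,95
Na,11,22.99,149
Mg,12,24.305,156
Al,13,26.982,166
Si,14,28.085,173
P,15,30.974,173
S,16,32.06,180
Cl,17,35.45,174
Ar,18,39.948,188
K,19,39.098,190
Ca,20,40.078,191
Ti,22,47.867,233
Fe,26,55.845,286
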