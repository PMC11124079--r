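symbol,atomic_number,covalent_radius
H,1,0.31
C,6,0.76
N,7,0.71
O,8,0.66
F,9,0.57
Na,11,1.66
Mg,12,1.41
Al,13,1.21
Si,14,1.11
P,15,1.07
S,16,1.05
Cl,17,1.02
K,19,2.03
Ca,20,1.76
Ti,22,1.60
V,23,1.53
Cr,24,1.39
Mn,25,1.50
Fe,26,1.52
Co,27,1.38
Ni,28,1.24
Cu,29,1.32
Zn,30,1.22
Zr,40,1.75
Ag,47,1.45
Sn,50,1.39
Ce,58,2.04
W,74,1.62
Au,79,1.36
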