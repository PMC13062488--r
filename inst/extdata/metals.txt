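Li
Na
K
Rb
Cs
Fr
Be
Mg
Ca
Sr
Ba
Ra
Al
Ga
In
Sn
Tl
Pb
Bi
Po
Sc
Ti
V
Cr
Mn
Fe
Co
Ni
Cu
Zn
Y
Zr
Nb
Mo
Tc
Ru
Rh
Pd
Ag
Cd
La
Ce
Pr
Nd
Sm
Eu
Gd
Tb
Dy
Ho
Er
Tm
Yb
Lu
Hf
Ta
W
Re
Os
Ir
Pt
Au
Hg
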