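name	smarts	tag
hydroxyl	[OX2H]	donor
primary_alcohol	[CX4H2][OX2H]	donor
secondary_alcohol	[CX4H1][OX2H]	donor
tertiary_alcohol	[CX4H0]([#6])([#6])[OX2H]	donor
phenol	c[OX2H]	donor
ether	[OX2H0]([#6])[#6]	acceptor
methoxy	[OX2][CH3]	acceptor
aldehyde	[CX3H1]=[OX1]	acceptor
ketone	[#6][CX3](=[OX1])[#6]	acceptor
carboxylic_acid	[CX3](=[OX1])[OX2H]	negative
carboxylate	[CX3](=[OX1])[OX1-]	negative
ester	[CX3](=[OX1])[OX2H0][#6]	acceptor
lactone	[C;R](=[OX1])[O;R]	acceptor
anhydride	[CX3](=[OX1])[OX2][CX3](=[OX1])	-
epoxide	[OX2r3]1[#6r3][#6r3]1	acceptor
carbonate	[OX2][CX3](=[OX1])[OX2]	-
enol_ether	[OX2][CX3]=[CX3]	-
primary_amine	[NX3;H2;!$(NC=[O,S,N])]	positive
secondary_amine	[NX3;H1;!$(NC=[O,S,N])]([#6])[#6]	positive
tertiary_amine	[NX3;H0;!$(NC=[O,S,N]);!$(N=O)]([#6])([#6])[#6]	positive
quaternary_ammonium	[NX4+]	positive
amide	[NX3][CX3]=[OX1]	-
lactam	[C;R](=[OX1])[N;R]	-
urea	[NX3][CX3](=[OX1])[NX3]	-
carbamate	[NX3][CX3](=[OX1])[OX2]	-
guanidine	[NX3][CX3](=[NX2])[NX3]	positive
amidine	[NX3][CX3]=[NX2]	positive
imine	[CX3]=[NX2]	-
nitrile	[NX1]#[CX2]	acceptor
nitro	[$([NX3](=O)=O),$([NX3+](=O)[O-])]	-
nitroso	[NX2]=[OX1]	-
azo	[NX2]=[NX2]	-
azide	[NX2]=[NX2+]=[NX1-]	-
hydrazine	[NX3][NX3]	-
hydrazone	[NX3][NX2]=[CX3]	-
hydroxylamine	[NX3][OX2H]	-
isocyanate	[NX2]=[CX2]=[OX1]	-
isothiocyanate	[NX2]=[CX2]=[SX1]	-
aniline	c[NX3]	-
n_oxide	[#7+][OX1-]	-
thiol	[SX2H]	donor
thioether	[SX2H0]([#6])[#6]	-
disulfide	[SX2][SX2]	-
sulfoxide	[#16X3]=[OX1]	acceptor
sulfone	[#16X4](=[OX1])=[OX1]	-
sulfonamide	[#16X4](=[OX1])(=[OX1])[NX3]	-
sulfonic_acid	[#16X4](=[OX1])(=[OX1])[OX2H]	negative
thiourea	[NX3][CX3](=[SX1])[NX3]	-
thioamide	[NX3][CX3]=[SX1]	-
phosphoryl	[PX4]=[OX1]	acceptor
phosphate_ester	[PX4](=[OX1])[OX2][#6]	negative
fluoroalkane	[CX4][F]	-
chloroalkane	[CX4][Cl]	hydrophobe
bromoalkane	[CX4][Br]	hydrophobe
iodoalkane	[CX4][I]	hydrophobe
aryl_halide	c[F,Cl,Br,I]	hydrophobe
trifluoromethyl	[CX4](F)(F)F	-
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]	-
alkene	[CX3]=[CX3]	-
alkyne	[CX2]#[CX2]	-
tert_butyl	[CX4]([CH3])([CH3])[CH3]	hydrophobe
pyridine	c1ccncc1	aromatic
pyrimidine	c1cncnc1	aromatic
pyrrole	c1cc[nH]c1	aromatic
furan	c1ccoc1	aromatic
thiophene	c1ccsc1	aromatic
imidazole	c1c[nH]cn1	aromatic
pyrazole	c1cc[nH]n1	aromatic
oxazole	c1ocnc1	aromatic
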