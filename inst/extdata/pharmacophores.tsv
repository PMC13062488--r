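name	smarts	tag
donor_hydroxyl	[OX2H]	donor
donor_amine	[NX3;H1,H2;+0]	donor
donor_thiol	[SX2H]	donor
donor_aromatic_nh	[nH]	donor
acceptor_carbonyl_o	[OX1]	acceptor
acceptor_ether_o	[OX2H0]	acceptor
acceptor_aromatic_n	[nX2]	acceptor
acceptor_tertiary_n	[NX3;H0;+0;!$(NC=[OX1]);!$(N=O)]	acceptor
aromatic_ring6	a1aaaaa1	aromatic
aromatic_ring5	a1aaaa1	aromatic
hydrophobe_chain	[CX4H2][CX4H2]	hydrophobe
hydrophobe_methyl	[CX4H3][#6]	hydrophobe
hydrophobe_halogen	[Cl,Br,I]	hydrophobe
pos_quaternary_n	[NX4+]	positive
pos_basic_amine	[NX3;H1,H2;+0;!$(NC=[OX1])]	positive
pos_guanidinium	[NX3][CX3](=[NX2])[NX3]	positive
neg_carboxyl	[CX3](=[OX1])[OX2H,OX1-]	negative
neg_sulfonate	[#16X4](=[OX1])(=[OX1])[OX2H,OX1-]	negative
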