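alert	smarts
acid_halide	[CX3](=O)[F,Cl,Br,I]
aldehyde	[CX3H1](=O)[#6]
acyl_hydrazine	[CX3](=O)[NX3][NX3]
alkyl_halide	[CX4][Cl,Br,I]
allene	C=C=C
azide	N=[N+]=[N-]
azo_group	[#6]N=N[#6]
carbo_cation_anion	[C+,C-]
conjugated_nitrile	C=CC#N
diazo_group	[N-]=[N+]=C
diketo_group	[#6]C(=O)C(=O)[#6]
disulfide	[SX2][SX2]
enol_ether_acyclic	[CX3;!R]=[CX3;!R][OX2][#6]
epoxide_aziridine_thiirane	C1[O,N,S]C1
halogenated_aromatic	c([F,Cl,Br,I])c([F,Cl,Br,I])
heavy_metal	[#80,#82,#33,#51,#50]
hydrazone	[#6]C=N[NX3]
hydroxamic_acid	C(=O)N[OX2H]
imine_acyclic	[CX3;!R]=[NX2;!R]
isolated_alkene	[CX3H2]=[CX3H1][CX4]
long_aliphatic_chain	[CH2][CH2][CH2][CH2][CH2][CH2][CH2]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
nitro_group	[N+](=O)[O-]
nitroso	[#6][NX2]=[OX1]
oxime	[CX3]=[NX2][OX2H]
oxygen_nitrogen_single_bond	[OX2;!$(O=*)][NX3]
peroxide	[OX2][OX2]
phenol_ester	c1ccccc1OC(=O)[#6]
phosphoric_ester	P(=O)(O)O
quaternary_nitrogen	[NX4+]
quinone	O=C1C=CC(=O)C=C1
silicon_halogen	[Si][F,Cl,Br,I]
sulfinic_acid	[SX3](=O)[OX2H]
sulfonic_acid	S(=O)(=O)[OX2H]
sulfonyl_halide	S(=O)(=O)[F,Cl,Br]
sulfur_nitrogen_single_bond	[SX2][NX3]
thioamide	[NX3][CX3]=[SX1]
thioester	[SX2][CX3]=[OX1]
thiol	[SX2H]
triphenyl_methyl	C(c1ccccc1)(c1ccccc1)c1ccccc1
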