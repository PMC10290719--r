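family	smarts
Donor	[N;!H0;v3;+0]
Donor	[N;!H0;+1;v4]
Donor	[O;H1;+0]
Donor	[S;H1;+0]
Donor	[n;H1;+0]
Acceptor	[O;H0;v2;!$(O=N-*)]
Acceptor	[O;H1;v2;+0]
Acceptor	[OX1;-]
Acceptor	[o;+0;!$([o]c=O)]
Acceptor	[N;v3;H0;+0;!$(N=*);!$(N-a);!$(N-C=[O,N,S])]
Acceptor	[n;H0;+0;!$([n]-[#6]=O)]
PosIonizable	[+;!$([+]~[-])]
PosIonizable	[NX3;H2;+0;!$(N-a);!$(N-[#6]=[O,N,S])]
PosIonizable	[NX3;H1;+0;!$(N-a);!$(N-[#6]=[O,N,S]);$(N(-C)-C)]
PosIonizable	[NX3;+0]([CX4])([CX4])[CX4]
PosIonizable	[NX3][CX3](=[NX2])[NX3]
NegIonizable	[CX3](=O)[OX1H0-,OX2H1]
NegIonizable	[SX4](=O)(=O)[OX1H0-,OX2H1]
NegIonizable	[PX4](=O)([OX1H0-,OX2H1])[OX1H0-,OX2H1]
NegIonizable	c1nnn[nH]1
ZnBinder	[S;D1;H1]-[#6]
ZnBinder	[#6]C(=O)[S;D1]
ZnBinder	[#6]C(=O)N[O;H1]
Aromatic	a1aaaaa1
Aromatic	a1aaaa1
Hydrophobe	[CX4;D3,D4;!$(C~[#7,#8,#9,#15,#16,#17,#35,#53])]
Hydrophobe	[Cl,Br,I]
Hydrophobe	[CX4H3][CX4H2][CX4H2]
Hydrophobe	[c]C(F)(F)F
Hydrophobe	[SX2](-[#6])-[#6]
LumpedHydrophobe	[R]1[R][R][R][R][R]1
LumpedHydrophobe	[R]1[R][R][R][R]1
LumpedHydrophobe	[CX4]([CX4H3])([CX4H3])[CX4H3]
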