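KEGG00190_OXIDATIVE_PHOSPHORYLATION	curated subset of oxidative phosphorylation pathway members	Ndufa1	Ndufa2	Ndufb4	Ndufs1	Ndufv1	Sdha	Sdhb	Uqcrc1	Uqcrc2	Uqcrfs1	Cycs	Cox4i1	Cox5a	Cox6b1	Cox7a2	Atp5a1	Atp5b	Atp5o	Atp6v0c	Ppa1
KEGG00010_GLYCOLYSIS	curated subset of glycolysis / gluconeogenesis pathway members	Hk1	Hk2	Gpi1	Pfkl	Pfkm	Aldoa	Aldoc	Tpi1	Gapdh	Pgk1	Pgam1	Eno1	Eno2	Pkm	Ldha	Ldhb	Pfkp	Bpgm	Galm	Pgm1
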