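property	group1	group2	group3
hydrophobicity	RKEDQN	GASTPHY	CLVIMFW
normalized.vdw.volume	GASTPDC	NVEQIL	MHKFRYW
polarity	LIFWCMVY	PATGS	HQRKNED
polarizability	GASDT	CPNVEQIL	KMHFRYW
charge	KR	ANCQGHILMFPSTWYV	DE
secondary.structure	EALMQKRH	VIYCWFT	GNPSD
solvent.accessibility	ALFCGIVW	RKQEND	MSPTHY
surface.tension	GQDNAHR	KTSEC	ILMFPWYV
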