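name	recognition	cut_top	cut_bottom
NaeI	GCCGGC	3	3
SfaNI	GCATC	10	14
AluI	AGCT	2	2
BamHI	GGATCC	1	5
DdeI	CTNAG	1	4
DraI	TTTAAA	3	3
EcoRI	GAATTC	1	5
EcoRV	GATATC	3	3
FokI	GGATG	14	18
HaeIII	GGCC	2	2
HgaI	GACGC	10	15
HhaI	GCGC	3	1
HindIII	AAGCTT	1	5
HinfI	GANTC	1	4
KpnI	GGTACC	5	1
MseI	TTAA	1	3
MspI	CCGG	1	3
NcoI	CCATGG	1	5
NdeI	CATATG	2	4
PstI	CTGCAG	5	1
RsaI	GTAC	2	2
SacI	GAGCTC	5	1
SalI	GTCGAC	1	5
ScaI	AGTACT	3	3
SmaI	CCCGGG	3	3
SphI	GCATGC	5	1
SspI	AATATT	3	3
Sau3AI	GATC	0	4
TaqI	TCGA	1	3
XbaI	TCTAGA	1	5
XhoI	CTCGAG	1	5
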