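gene	GATA4	HAND1	NKX2-5	TCF8
ACTC1	0	0	2	0
CAMK2A	0	0	2	1
CAMK2D	0	1	2	1
CSRP3	1	1	5	1
FHL2	1	0	8	3
GATA4	0	0	0	0
HAND1	1	1	1	1
KLF2	0	0	3	0
LAMA4	0	1	0	1
MYBPC3	0	0	2	1
MYH7	0	0	2	1
MYL2	0	0	2	1
MYL3	0	2	4	2
MYL9	0	1	0	0
MYOM1	1	0	4	1
NKX2-5	0	0	2	3
PLN	2	0	5	3
PPARGC1A	1	0	3	1
PRKAA1	0	0	2	1
PRKAG2	0	1	4	2
SMPX	0	2	2	1
TMOD1	0	0	3	1
TNNC1	0	1	2	2
TNNT2	0	0	1	0
TPM1	1	1	0	1
ZEB1	1	0	1	2
ZMYND11	2	0	2	3
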