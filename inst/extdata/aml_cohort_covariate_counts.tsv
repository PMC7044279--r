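category	level	count_low	count_high
molecular	IDH1	7	4
molecular	IDH2	5	6
molecular	NPM1c	24	31
molecular	FLT3-ITD	22	29
molecular	FLT3-TKD	17	7
molecular	NRAS	22	4
molecular	KRAS	4	0
molecular	EVI1	2	11
molecular	CEBPA	18	0
karyotype	+8	10	4
karyotype	-5/7q	6	10
karyotype	-9q	5	0
karyotype	11q23	5	3
karyotype	complex	8	0
karyotype	NN	50	31
karyotype	Other	14	9
karyotype	abn(3q)	0	1
karyotype	failure	1	4
karyotype	idt(16)	23	1
karyotype	t(15;17)	1	0
karyotype	t(6;9)	0	1
karyotype	t(8;21)	32	0
karyotype	t(9;22)	1	0
FAB	M0	8	3
FAB	M1	25	27
FAB	M2	39	20
FAB	M4	36	8
FAB	M5	39	8
FAB	M6	0	1
FAB	unknown	3	0
sex	Male	80	31
sex	Female	80	41
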