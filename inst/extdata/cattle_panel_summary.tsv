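group	breed	animals	markers
taurine	ANG	31	41580
taurine	BWS	34	39780
taurine	JER	260	35269
taurine	HOL	107	38946
indicine	BRA	30	31284
indicine	GIR	127	24062
indicine	IND	45	28776
indicine	NEL	23	69448
indicine	SIN	92	32264
indicine	TAB	49	69808
locally_adapted	CCD	55	37108
locally_adapted	CCB	24	36353
locally_adapted	CRI	62	40796
locally_adapted	CUR	17	30332
locally_adapted	FRA	54	35444
locally_adapted	MOC	20	38266
locally_adapted	PAN	49	36641
synthetic	CAN	121	37174
synthetic	GIO	120	47295
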