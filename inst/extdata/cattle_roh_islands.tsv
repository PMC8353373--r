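group	breed	chr	begin_bp	end_bp	length_bp	n_snp	roh_freq_pct
taurine	JER	7	42096163	43741249	1645086	17	68
indicine	BRA	14	23498304	23964115	465811	9	63
indicine	IND	6	36614641	40780850	4166209	35	58
indicine	TAB	1	2210624	3033433	823	30	55
locally_adapted	CCD	20	38452484	39965197	1512713	21	69
locally_adapted	CCB	20	38108826	38675350	566524	9	79
locally_adapted	CUR	11	54590248	60271069	5680821	57	59
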