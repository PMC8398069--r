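n_class	trait	chrom	cum_pos	marker	minus_log10_p	explained_var_pct
cm	AUC	5	316045624	PotVar0079081	8.16	24.43
cm	mt_as	5	316045624	PotVar0079081	8.46	25.10
cm	t2	5	316307819	PotVar0080570	6.73	16.16
cm	TbnB	3	216014512	solcap_snp_c2_616	5.12	15.72
cm	te	5	316045624	PotVar0079081	7.76	23.18
cm	Y_DM	5	316611906	solcap_snp_c2_50302	6.17	17.20
cm	SCYi	1	4041250	PotVar0045583	8.27	21.18
cm	SCYi	2	131733600	PotVar0120916	5.96	18.04
cm	SCYi	5	314920671	PotVar0025024	5.23	15.31
cm	SCYi	11	757973524	PotVar0112496	7.17	20.40
cm	N	5	316307819	PotVar0080570	6.36	19.29
HN	AP1	2	127511213	solcap_snp_c2_15749	4.61	11.28
HN	AP1	2	135122688	PotVar0046300	5.33	12.33
HN	AP1	5	315893706	PotVar0026425	5.70	14.33
HN	AP2	5	316045624	PotVar0079081	5.33	18.00
HN	t1	1	46273159	PotVar0132293	4.82	11.35
HN	t1	2	127511213	solcap_snp_c2_15749	5.28	13.23
HN	t1	2	135122688	PotVar0046300	5.23	12.00
HN	t1	5	315893706	PotVar0026425	6.95	16.68
HN	t2-t1	5	316045624	PotVar0079081	5.16	17.23
HN	TbnA	2	134943142	PotVar0045853	4.24	10.77
HN	TbnA	2	146198944	PotVar0002966	5.07	12.61
HN	TbnA	3	203612959	solcap_snp_c1_3637	5.88	13.38
HN	TbnMX	12	832589670	PotVar0052600	5.08	15.99
HN	TbwA	2	134242234	PotVar0128476	9.59	19.71
HN	TbwMX	2	134943142	PotVar0045853	6.14	15.09
HN	tm1	1	32843979	PotVar0000007	4.62	13.17
HN	tm1	6	427042067	PotVar0040538	5.12	13.61
HN	tm1	11	751753201	solcap_snp_c2_44269	4.70	13.56
HN	tm1	11	757973524	PotVar0112496	5.35	15.86
HN	Y_DM	9	627531669	PotVar0094025	4.56	14.51
HN	Y_DM	12	823287226	PotVar0037640	4.38	12.39
HN	SCYi	1	30559567	PotVar0037260	4.65	13.53
HN	SCYi	1	61310626	solcap_snp_c2_20888	5.04	15.92
HN	SCYi	8	543834623	PotVar0060623	5.30	15.34
LN	DM	7	484592357	PotVar0092426	7.48	11.85
LN	DM	7	490792384	solcap_snp_c2_38787	4.09	20.97
LN	mt_as	3	204691153	solcap_snp_c2_29678	4.37	14.45
LN	t2-t1	4	283407138	PotVar0116182	4.21	10.32
LN	TbnA	6	424940350	solcap_snp_c2_56145	5.44	13.99
LN	TbnB	6	425163888	PotVar0074198	4.20	13.30
LN	TbnB	10	695881376	solcap_snp_c1_13524	5.57	11.05
LN	TbnMX	3	216014512	solcap_snp_c2_616	4.34	11.33
LN	TbwB	3	217632046	PotVar0021118	5.84	18.26
LN	TbwB	6	424915228	PotVar0074004	5.17	15.42
LN	TbwB	10	695881376	solcap_snp_c1_13524	5.27	11.14
LN	TbwMX	2	106818648	solcap_snp_c2_4515	4.29	11.05
LN	te-t2	5	316045624	PotVar0079081	6.53	19.22
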