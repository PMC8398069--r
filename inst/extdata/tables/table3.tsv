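chrom	cum_pos	marker	trait	n_class	logp_uncorrected	ev_uncorrected	logp_corrected	ev_corrected
1	4041250	PotVar0045583	SCYi	cm	8.27	21.18	9.65	22.06
1	4041250	PotVar0045583	tm1	LN	NA	NA	6.36	14.49
1	32843979	PotVar0000007	SCYi	HN	4.74	12.93	4.91	13.58
1	32843979	PotVar0000007	tm1	HN	4.62	13.17	4.92	13.82
1	63469625	solcap_snp_c1_9676	SCYi	HN	5.07	14.44	5.59	15.39
1	81815164	PotVar0060997	TbnA	HN	NA	NA	5.60	14.32
2	127511213	PotVar0060997	t1	HN	5.28	13.23	5.33	11.55
2	131733600	PotVar0120916	SCYi	cm	5.96	18.04	6.93	17.51
2	134242234	PotVar0128476	TbwA	HN	9.59	19.71	9.31	20.68
2	134943142	PotVar0045853	TbnA	HN	4.24	10.77	4.29	10.80
2	134943142	PotVar0045853	TbwMX	HN	6.14	15.09	6.36	15.32
2	146198944	PotVar0002966	TbnA	HN	5.07	12.61	5.67	14.50
2	146303689	PotVar0003077	SCYi	HN	NA	NA	4.19	10.62
3	166741184	solcap_snp_c1_15204	DM	cm	NA	NA	5.43	13.98
3	203612959	solcap_snp_c1_3637	TbnA	HN	5.88	13.38	5.60	12.92
3	212481799	PotVar0030333	N	HN	NA	NA	4.33	12.00
3	212547269	PotVar0030515	te-t2	LN	NA	NA	4.49	10.32
3	212548683	PotVar0030515	te-t2	HN	NA	NA	5.08	11.57
3	213525966	PotVar0121169	N	LN	NA	NA	4.61	10.65
3	216081835	solcap_snp_c1_151	TbnB	cm	5.12	15.72	5.38	16.01
3	216081835	solcap_snp_c1_151	TbnMX	LN	4.34	11.33	4.73	11.96
3	217630938	solcap_snp_c1_151	TbwB	LN	5.85	18.74	5.28	17.75
4	283533011	solcap_snp_c1_15513	AP2	LN	NA	NA	4.46	10.31
4	285470025	PotVar0088487	Vx	LN	NA	NA	4.90	11.19
4	289210701	solcap_snp_c2_39807	DM	HN	NA	NA	4.84	11.99
4	300280572	PotVar0015935	TbwMX	HN	NA	NA	5.21	10.61
5	314920671	PotVar0025024	SCYi	cm	5.23	15.31	5.83	15.50
5	360216448	PotVar0082077	SCYi	HN	NA	NA	4.09	12.72
6	424406145	PotVar0082077	TbwB	LN	5.02	14.67	4.46	12.57
6	424940350	solcap_snp_c2_56145	TbnA	LN	5.44	13.99	4.40	12.65
6	427042067	PotVar0040538	tm1	HN	5.12	13.61	5.22	13.84
8	543834623	PotVar0060623	SCYi	HN	5.30	15.34	5.52	15.66
9	624408926	PotVar0051600	AP3	LN	NA	NA	4.54	10.23
10	695881376	PotVar0051600	TbwB	LN	5.27	11.14	5.57	11.22
10	695908422	solcap_snp_c2_57635	TbnB	LN	5.57	11.15	5.97	11.16
11	719755658	solcap_snp_c2_33657	NUpt	LN	NA	NA	5.09	12.32
11	724842000	PotVar0058777	SCYi	HN	NA	NA	4.46	12.67
11	751753201	solcap_snp_c2_44269	tm1	HN	4.70	13.56	5.24	14.68
11	757973524	PotVar0112496	SCYi	cm	7.17	20.40	7.34	21.01
12	823269906	PotVar0037718	t1	LN	NA	NA	4.21	10.98
12	827080788	solcap_snp_c1_11644	mt_as	HN	NA	NA	4.58	11.04
12	832202879	PotVar0052761	TbnA	LN	NA	NA	4.13	10.59
12	832589670	PotVar0052600	TbnMX	HN	5.08	15.99	5.13	15.96
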