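gene_id	tss_pos	p_value	fold_change	de_call	h3ac_common	extension	s5p_status	sp1_status	cpg	tata	expected_group
CCL1	32691253	3.50e-02	3.10	up	NO	none	none	none	NO	NO	1
CCL4	34431220	5.20e-04	29.59	up	NO	none	plus_only	none	NO	YES	1
CCL18	34391643	9.62e-05	2.76	up	NO	none	none	none	NO	YES	1
CCL20	228678558	4.50e-03	5.97	up	NO	none	plus_only	none	NO	YES	1
CCL22	57392718	4.80e-02	2.18	up	NO	none	none	none	NO	NO	1
CD40	44746906	2.15e-04	3.66	up	YES	both	plus_only	plus_only	YES	NO	2
CSF1	110453233	4.59e-02	2.27	up	YES	upstream	minus_only	none	YES	NO	2
CXCL1	74735109	5.30e-03	14.09	up	YES	downstream	plus_only	none	YES	YES	2
CXCL2	74965998	1.94e-07	24.61	up	YES	downstream	plus_only	none	YES	NO	2
F3	95007371	3.25e-03	2.12	up	YES	none	minus_only	plus_only	YES	NO	2
ICAM1	10381517	8.44e-04	4.97	up	YES	both	both	none	YES	NO	2
IL1B	113594356	8.40e-03	2.12	up	YES	downstream	none	none	NO	YES	2
IRAK2	10206563	5.01e-04	5.17	up	YES	both	both	none	YES	NO	2
NFKB1	103422486	2.00e-04	3.35	up	YES	none	both	none	YES	NO	2
NFKB2	104155500	2.00e-03	2.46	up	YES	both	none	both	YES	NO	2
NFKB2	104154229	2.00e-03	2.46	up	YES	both	none	none	YES	NO	2
NFKBIA	35874347	1.42e-04	6.44	up	YES	both	both	none	YES	NO	2
NFKBIZ	101568358	2.85e-06	21.95	up	YES	both	both	both	YES	NO	2
PTGS2	186650560	5.30e-04	26.32	up	YES	downstream	both	none	YES	YES	2
PTX3	157154580	1.08e-03	7.10	up	YES	upstream	both	none	YES	NO	2
SOCS3	76356158	5.83e-07	3.84	up	YES	both	both	plus_only	YES	NO	2
TNF	31543350	6.87e-06	47.23	up	YES	both	minus_only	none	NO	YES	2
TNFAIP2	103592664	4.46e-05	13.37	up	YES	both	none	none	YES	NO	2
TNFAIP2	103599087	4.46e-05	13.37	up	YES	both	none	none	NO	NO	2
TNFAIP3	138188581	1.09e-05	9.15	up	YES	upstream	both	both	YES	NO	2
TNFAIP8	118604418	1.23e-03	4.19	up	YES	downstream	both	both	YES	NO	2
TNFAIP8	118691596	1.23e-03	4.19	up	YES	upstream	plus_only	none	YES	NO	2
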