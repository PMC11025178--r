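pair_id	model	eo_hr	eo_lo	eo_hi	lo_hr	lo_lo	lo_hi	i2_printed	p_het_printed	p_cmp
prs269_all	wcox	2.35	1.99	2.78	1.95	1.89	2.01	79	0.031	eq
prs269_fh_negative	wcox	2.26	1.87	2.72	1.92	1.85	1.98	65	0.093	eq
prs269_fh_positive	wcox	2.63	1.57	4.41	1.97	1.81	2.14	15	0.278	eq
general_prs	wcox	1.99	1.69	2.34	1.77	1.72	1.83	47	0.170	eq
eopc_prs	wcox	4.70	3.98	5.54	0.98	0.96	1.01	100	0.001	lt
lopc_prs	wcox	1.70	1.46	1.99	1.75	1.70	1.81	0	0.709	eq
prs269_case_control	logistic	2.35	2.16	2.54	1.96	1.91	2.01	94	0.001	lt
merged_eopc_prs	wcox	5.16	4.37	6.08	1.03	1.00	1.06	100	0.001	lt
merged_lopc_prs	wcox	1.75	1.49	2.04	1.80	1.75	1.86	0	0.679	eq
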