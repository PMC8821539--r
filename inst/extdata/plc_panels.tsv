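# Per-target calibration summaries for eight protein-ligand panels
# r_squared / se: least-squares fit of dG_e on DFE over the target's ligand set
# (se in kcal/mol); slope/intercept: the printed fitted relationship.
# Thrombin: r_squared_excl / se_excl are the values after excluding its two
# outlier ligands, and its printed slope/intercept correspond to that fit.
target	n_ligands	cv	n_runs	t_ns	r_squared	se	slope	intercept	r_squared_excl	se_excl
CDK2	16	F80	40	20	0.67	0.72	0.858	7.26	NA	NA
TYK2	16	M978	50	10	0.66	0.79	0.602	-0.85	NA	NA
P38a	34	L75	40	20	0.6	0.65	0.39	-3.33	NA	NA
JNK1	21	L110	27	10	0.51	0.62	0.559	-2.86	NA	NA
MCL1	42	R290	30	10	0.48	0.78	0.642	-1.96	NA	NA
PTP1B	23	R221	40	15	0.35	1.09	0.628	4.19	NA	NA
BACE	36	W176	40	20	0.32	0.65	0.268	-4.18	NA	NA
Thrombin	11	S214	50	10	0.01	0.57	0.793	0.37	0.62	0.36
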