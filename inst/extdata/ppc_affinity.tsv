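# 19 non-congeneric protein-protein complexes: calculated DFE vs experimental affinity
# dfe, dfe_err, dg_calc, dg_exp in kcal/mol at printed precision; kd in molar
# dg_exp = kT ln(kd) at 310 K; 3SGB is the documented calibration outlier
complex_id	ppi_type	cv	dfe	dfe_err	dg_calc	dg_exp	kd
1EMV	IM9 immunity protein-Colicin E9 nuclease	V37A-F86B	-32.42	0.16	-15.65	-19.32	2.4e-14
2PTC	Trypsin-BPTI	D194E-K50I	-36.59	0.27	-17.53	-18.75	6e-14
1BVN	alpha-Amylase-Tendamistat	D300P-A823T	-34.67	0.07	-16.66	-15.65	9.2e-12
1R0R	A serine protease-OMTKY3	L126E-T17I	-32.38	0.13	-15.63	-14.94	2.94e-11
1ACB	Chymotrypsin-Eglin C	S214E-L45I	-29.38	0.2	-14.27	-13.76	2e-10
1AY7	Rnase SA-Barstar	T82A-L20B	-28.54	0.18	-13.9	-13.76	2e-10
2UUY	Trypsin-Tryptase inhibitor	D196E-K39I	-24.11	0.32	-11.9	-11.7	5.6e-9
1KAC	Adenovirus protein-Human receptor	L430A-W59B	-23.99	0.16	-11.84	-11.11	1.48e-8
3BZD	TCR Vbeta8.2-Enterotoxin C-3	F75A-M24B	-17.73	0.23	-9.02	-9.95	9.6e-8
2C0L	PEX5-SCP2	S612A-L31B	-14.56	0.15	-7.59	-9.88	1.09e-7
1KTZ	TGFbeta-TGFbeta receptor	V33A-T51B	-20.78	0.05	-10.39	-9.27	2.9e-7
3LVK	Cys desulfurase-Sulfurtransferase	D52A-R27B	-17.72	0.17	-9.01	-9.25	3e-7
1FFW	Chemotaxis protein CheY-Chemotaxis protein CheA	L84A-L212B	-14.46	0.07	-7.54	-8.33	1.35e-6
3F1P	HIF2A-ARNT	V340A-I458B	-20.83	0.47	-10.42	-8.3	1.4e-6
1US7	HSP90-P50	F104A-L205B	-17.59	0.16	-8.96	-8.28	1.46e-6
3A4S	UBC9-SLD2	I45B-I408C	-13.61	0.17	-7.16	-7.87	2.81e-6
1QA9	CD2-CD58	K91A-D33B	-20.74	0.12	-10.38	-7.16	9e-6
2OOB	CBL-B-Ubiquitin	L69B-A937A	-9.81	0.15	-5.44	-5.99	6e-5
3SGB	Proteinase B-OMTKY3	L18I-S195E	-18.84	0.03	-9.52	-15.24	1.79e-11
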