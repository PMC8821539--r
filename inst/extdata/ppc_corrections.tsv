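# DFE and calibrated binding free energy before (nc) and after the one-way-trip
# correction process; n_runs = replica count, t_ns = per-run chemical time before
# any extension; energies in kcal/mol at printed precision
complex_id	n_runs	t_ns	corrections	dfe	dfe_nc	dg_calc	dg_calc_nc
1EMV	50	40	No corrections	-32.42	-32.42	-15.65	-15.57
2PTC	50	20	18 runs extended to 30 ns; 2 runs to 40 ns	-36.59	-35.95	-17.53	-17.43
1BVN	50	40	No corrections	-34.67	-34.67	-16.66	-16.57
1R0R	50	20	No corrections	-32.38	-32.38	-15.63	-15.55
1ACB	50	30	No corrections	-29.38	-29.38	-14.27	-14.22
1AY7	60	40	13 runs with Invasions removed	-28.54	-30.76	-13.9	-14.36
2UUY	50	20	4 runs extended to 30 ns	-24.11	-24.14	-11.9	-11.88
1KAC	50	30	No corrections	-23.99	-23.99	-11.84	-11.82
3BZD	50	20	3 runs with Invasions removed	-17.73	-17.77	-9.02	-9.04
2C0L	50	20	13 runs with repeated sampling removed	-14.56	-15.9	-7.59	-7.61
1KTZ	50	20	8 runs extended to 30 ns	-20.78	-20.79	-10.39	-10.39
3LVK	50	20	3 runs with repeated sampling removed; 11 runs extended to 30 ns; 2 runs to 40 ns	-17.72	-16.89	-9.01	-9.02
1FFW	50	10	11 runs with repeated sampling removed; 6 runs extended to 20 ns	-14.46	-13.24	-7.54	-7.03
3F1P	50	30	7 runs with repeated sampling removed; 2 runs extended to 40 ns	-20.83	-20.31	-10.42	-10.41
1US7	50	10	No corrections	-17.59	-17.59	-8.96	-8.96
3A4S	50	10	2 runs with Invasions removed; 17 runs extended 20 ns	-13.61	-14.42	-7.16	-7.55
1QA9	50	20	No Corrections	-20.74	-20.74	-10.38	-10.37
2OOB	50	10	2 runs with repeated sampling removed; 5 runs extended to 20 ns	-9.81	-9.54	-5.44	-5.5
3SGB	50	40	No correction	-18.84	-18.84	-9.52	-8.96
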