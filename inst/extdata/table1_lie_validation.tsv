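pdb_id	resolution	ligand	ic50_nM	dg_exp	dg_lie	dg_lie_sem
6CQV	2.60	HI6	636000	-4.39	-10.33	0.36
4M0E	2.00	dihydrotanshinone I	1000	-8.24	-11.02	0.15
4EY6	2.40	galantamine	100	-9.61	-10.63	0.14
4EY5	2.30	huperzine A	21	-10.54	-12.18	0.19
6O50	2.35	EBW	8	-11.11	-12.84	0.40
4M0F	2.30	territrem B	6	-11.29	-13.48	0.54
7D9Q	2.66	H1R	3	-11.70	-12.08	0.82
7D9O	2.45	H0L	3	-11.77	-12.76	0.20
4EY7	2.35	donepezil	2	-11.94	-12.43	0.72
7D9P	2.85	H0R	0.86	-12.44	-11.87	0.61
		CID54414454			-10.45	0.26
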