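individual_id	reactive	learning_rate	learning_impediment	exploratory_adaptiveness	handedness	drs_cross	drs_parallel	fgcm_ng_g	age_years	sex	body_mass_kg
E Mei	3.12	0.59	-0.25	-1.71	L	105	1	442.5	3	F	101
Lin Xi	-0.25	-0.66	-0.13	-1.23	L	86	119	474.08	2	M	69
Mao Mao	-0.78	0.13	0.8	-0.54	L	17	1	302.48	2	M	60
Mu Ye	1.71	0.46	0.77	-1.17	L	151	79	489.22	4	M	108
Nong Nong	1.87	-1.04	2.47	-1.46	N	83	98	410.24	3	M	112
Qing Qing	0.4	1	-1.73	0.8	L	16	17	326.42	8	M	120
Su Yang	-1.91	-0.53	1.65	1.54	R	32	35	165.94	4	M	100
Xing Ye	-1.8	1.09	-0.4	1.77	R	48	111	256.52	4	M	119
Xing Yue	-0.33	0.79	-1.9	-0.08	L	137	1	321.96	4	M	121
Yun Yun	-0.47	-2.35	2.38	1.51	L	23	7	166.84	14	M	135
Zhu Ling	-1.57	0.53	-2	1.85	R	45	2	187.48	16	F	116
Ling Lang			-1.66	-1.28	R	27	19	479.33	5	F	99
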