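sample_id	elevation_m	fgcm_ng_g	individual_id	ssd_km
Q-D-9	2708	9.3	G	7.05
Q-D-10	2733	16.6	A	27.94
Q-D-11	2712	119.8	A	7.05
Q-D-12	2695	93.1	A	9.85
Q-D-13	2713	8.1	H	22.87
Q-D-14	2698	40.6	B	8.90
Q-D-15	2713	27.5	I	19.13
Q-D-16	2675	173.9	C	28.95
Q-D-17	2695	120.2	B	10.94
Q-D-18	2676	119.8	H	5.07
Q-D-20	2706	8.5	E	6.05
Q-D-21	2703	43.6	D	27.94
Q-D-25	2652	31.2	D	8.90
Q-D-26	2594	29.4	A	19.13
Q-D-27	2593	21.7	A	27.60
Q-D-29	2663	83.1	A	8.84
Q-D-30	2523	12.1	A	32.71
Q-D-32	2609	103.9	F	25.88
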