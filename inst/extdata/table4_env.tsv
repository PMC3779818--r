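station_id	temperature	salinity	fluorescence	dissolved_fe	bottom_depth
2	9.45	30.6	4.06	1.30	209
5	10.1	30.1	4.03	1.30	209
7	8.45	31.9	1.17	1.45	2260
9	8.89	32.1	1.56	0.30	2610
10	8.61	32.2	1.49	0.14	2668
11	8.47	32.1	0.27	0.16	2692
12	8.53	32.1	0.45	0.17	2906
13	8.84	32.2	1.00	0.16	3005
14	8.55	32.2	0.41	0.13	3191
15	8.49	32.2	0.18	0.12	3379
17	8.59	32.1	0.13	0.16	2692
19	6.34	32.6	0.65	0.08	4226
25	6.49	32.6	0.50	0.08	4226
26	8.85	31.8	2.28	1.64	352
27	9.42	32.1	1.93	1.73	768
28	9.60	32.1	0.94	1.68	1547
29	11.7	30.7	0.70	1.40	252
30	10.2	31.7	1.02	1.59	2138
31	10.2	32.0	1.56	1.76	907
32	9.59	32.1	1.18	0.30	2926
33	9.45	32.2	1.26	0.12	2608
34	9.37	32.1	0.28	0.11	2691
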