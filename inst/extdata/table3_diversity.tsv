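sample_id	H	S	J
5	0.77	10	0.77
29B	0.75	9	0.78
29A	0.74	9	0.77
32	0.71	6	0.91
26	0.70	9	0.73
2	0.67	9	0.70
8	0.66	7	0.78
30	0.64	7	0.76
17	0.62	6	0.80
10	0.62	6	0.80
33	0.62	6	0.79
12	0.62	5	0.88
9	0.61	6	0.79
19	0.59	5	0.85
35	0.58	6	0.74
25	0.57	6	0.73
11A	0.56	7	0.66
13B	0.56	7	0.66
11B	0.54	7	0.64
13A	0.52	6	0.66
15	0.51	5	0.74
34	0.51	5	0.73
14	0.46	5	0.66
27	0.33	4	0.55
28	0.28	5	0.41
31	0.28	4	0.46
7	0.12	2	0.40
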