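bin_id	low	high	taxon_labels	branch_labels
1	348	349	T. oceanica
2	357	358
3	362	363
4	366	367		d
5	368	369	Skeletonema
6	374	375	Minidiscus;Skeletonema
7	377	378	CCMP1616;Skeletonema
8	384	385	T. minuscula	e;g
9	386	387	T. punctigera;T. rotula;Skeletonema	f;i;j
10	388	389	T. anguste-lineata;CCMP1004	h;k
11	390	391	T. aestivalis
12	393	394	T. guillardii;T. pseudonana
13	396	397	T. weissflogii
14	402	403
15	404	405		c
16	409	410	C. atlanticus	a;b
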