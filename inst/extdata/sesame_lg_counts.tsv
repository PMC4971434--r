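lg	length_bp	snp_baizhima	rate_snp_baizhima	snp_mishuozhima	rate_snp_mishuozhima	indel_baizhima	rate_indel_baizhima	indel_mishuozhima	rate_indel_mishuozhima
1	18577331	81285	4.38	65543	3.53	26939	1.45	23969	1.29
2	18500646	49964	2.70	51768	2.80	18627	1.01	18429	1.00
3	24928530	159130	6.38	156471	6.28	52441	2.10	51437	2.06
4	17356267	83379	4.80	82983	4.78	29392	1.69	29372	1.69
5	18898134	163548	8.65	145640	7.71	60563	3.20	54592	2.89
6	25289714	91586	3.62	100394	3.97	38274	1.51	39506	1.56
7	11725536	51181	4.36	53081	4.53	17002	1.45	17849	1.52
8	21523998	69132	3.21	59884	2.78	24673	1.15	22233	1.03
9	12411895	47237	3.81	39152	3.15	18759	1.51	16006	1.29
10	17245970	57009	3.31	56988	3.30	23251	1.35	22572	1.31
11	15446199	57290	3.71	53268	3.45	21503	1.39	19525	1.26
12	6373461	7353	1.15	9978	1.57	3182	0.50	3861	0.61
13	5050363	16447	3.26	21632	4.28	6100	1.21	7347	1.45
14	4882680	10683	2.19	6763	1.39	4330	0.89	3044	0.62
15	10047770	21933	2.18	21060	2.10	8212	0.82	8018	0.80
16	4963887	22773	4.59	26632	5.37	8909	1.79	9599	1.93
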