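id	abbrev	x	y	z
1	PreCG.L	-44.5	43.1	-21.6
2	PreCG.R	44.5	43.1	-21.6
3	SFG.L	-34.5	46.2	62.6
4	SFG.R	34.5	46.2	62.6
5	MFG.L	-19	-44.9	13.9
6	MFG.R	19	-44.9	13.9
7	IFGoperc.L	-12.2	31.3	61.2
8	IFGoperc.R	12.2	31.3	61.2
9	IFGtriang.L	-12	4.8	54.9
10	IFGtriang.R	12	4.8	54.9
11	IFGorb.L	-22.3	-12.3	32.6
12	IFGorb.R	22.3	-12.3	32.6
13	ROL.L	-39.4	18.1	62.4
14	ROL.R	39.4	18.1	62.4
15	SMA.L	-8	-66.1	30.7
16	SMA.R	8	-66.1	30.7
17	OLF.L	-17.8	7	5
18	OLF.R	17.8	7	5
19	SFGmedial.L	-51.9	13.7	6.2
20	SFGmedial.R	51.9	13.7	6.2
21	PFCventmed.L	-51.5	-20.9	10.9
22	PFCventmed.R	51.5	-20.9	10.9
23	REC.L	-42.5	15.7	45.6
24	REC.R	42.5	15.7	45.6
25	INS.L	-23.7	45.9	-21.5
26	INS.R	23.7	45.9	-21.5
27	ACC.L	-32.2	-49.2	42.4
28	ACC.R	32.2	-49.2	42.4
29	MCC.L	-43	-20.3	36
30	MCC.R	43	-20.3	36
31	PCC.L	-37.1	46.6	-9.6
32	PCC.R	37.1	46.6	-9.6
33	HIP.L	-37.4	52	-1.5
34	HIP.R	37.4	52	-1.5
35	PHG.L	-18.2	-68.6	21.3
36	PHG.R	18.2	-68.6	21.3
37	AMY.L	-18.2	-18.5	35.8
38	AMY.R	18.2	-18.5	35.8
39	CAL.L	-26.3	-6.6	63.5
40	CAL.R	26.3	-6.6	63.5
41	CUN.L	-52.3	41.6	43.4
42	CUN.R	52.3	41.6	43.4
43	LING.L	-53.2	-65.6	26
44	LING.R	53.2	-65.6	26
45	SOG.L	-42.8	53.4	51.5
46	SOG.R	42.8	53.4	51.5
47	MOG.L	-42.5	47.5	-7.9
48	MOG.R	42.5	47.5	-7.9
49	IOG.L	-33.2	-73.5	-0.6
50	IOG.R	33.2	-73.5	-0.6
51	FFG.L	-8.1	-13	49.5
52	FFG.R	8.1	-13	49.5
53	PoCG.L	-36.6	-30.4	37.4
54	PoCG.R	36.6	-30.4	37.4
55	SPG.L	-47.3	41.8	-3.4
56	SPG.R	47.3	41.8	-3.4
57	IPG.L	-43.3	-22.4	-21.1
58	IPG.R	43.3	-22.4	-21.1
59	SMG.L	-29.3	32	-12.4
60	SMG.R	29.3	32	-12.4
61	ANG.L	-33.2	18.3	-5.5
62	ANG.R	33.2	18.3	-5.5
63	PCUN.L	-33.3	28.5	18.1
64	PCUN.R	33.3	28.5	18.1
65	PCL.L	-8.1	-30.7	-7.2
66	PCL.R	8.1	-30.7	-7.2
67	CAU.L	-24.7	10.9	39.7
68	CAU.R	24.7	10.9	39.7
69	PUT.L	-36.8	-84.4	-24.3
70	PUT.R	36.8	-84.4	-24.3
71	PAL.L	-47	31.6	8.8
72	PAL.R	47	31.6	8.8
73	THA.L	-24.8	-84	21.3
74	THA.R	24.8	-84	21.3
75	HES.L	-27.3	-55.9	-24.9
76	HES.R	27.3	-55.9	-24.9
77	STG.L	-35	41.9	27.3
78	STG.R	35	41.9	27.3
79	TPOsup.L	-35.7	0.6	-10.8
80	TPOsup.R	35.7	0.6	-10.8
81	MTG.L	-41.8	-31.9	7.3
82	MTG.R	41.8	-31.9	7.3
83	ITG.L	-26.6	-24	33.1
84	ITG.R	26.6	-24	33.1
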