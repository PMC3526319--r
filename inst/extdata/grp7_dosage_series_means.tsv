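primer_pair	agi	description	product_sizes	kd_small	kd_large	p_kd	wt_small	wt_large	ox_small	ox_large	p_ox	grp8ox_small	grp8ox_large	p_grp8ox
#12	At1g72320	APUM23 pumilio RNA binding	141/150/215	21	77	0.0001	15	83	5	95	0.0002	7	93	0.0099
#19	At2g32320	tRNA His guanylyltransferase	202/273	27	73	0.0051	33	67	45	55	0.0047	35	65	0.2379
#288	At3g12570	FYD	159/188	33	67	0.0111	43	57	52	48	0.0148	44	56	0.5852
#75	At2g36000	mTERF-related	150/254	40	60	0.0076	31	69	14	86	0.0009	22	78	0.0098
#90	At4g39260	AtGRP8 GR-RBP8	158/316	99	1	0.0060	94	6	23	77	0.0000	98	2	0.0215
#343	At3g29160	AKIN11 protein kinase	159/307	57	43	0.0001	30	70	3	97	0.0008	11	89	0.0027
#181	At5g05550	transcription factor	210/308	50	50	0.0049	64	36	74	26	0.0143	67	33	0.2237
#226	At4g24740	AFC2 LAMMER kinase	143/309	7	93	0.0004	19	81	47	53	0.0020	33	67	0.0506
#227	At4g24740	AFC2 LAMMER kinase	152/343	22	78	0.0125	30	70	73	27	0.0000	53	47	0.0155
#327	At5g59950	Aly/REF export factor	226/422	90	10	0.0102	84	16	50	50	0.0020	68	32	0.0456
#129	At2g40830	RHC1A RING-H2 finger	220/329	94	6	0.0441	91	9	59	41	0.0012	76	24	0.0648
#171	At5g18620	CHR17 chromatin remodeling	213/222	75	25	0.0179	72	28	66	34	0.0005	71	29	0.4350
#273	At3g07810	hnRNP putative	126/173	12	88	0.0184	8	92	3	97	0.0094	5	95	0.0108
#295	At2g02390	ATGSTZ1 glutathione transferase	181/202	91	9	0.0165	88	12	69	31	0.0023	74	26	0.0512
#322	At2g33480	ANAC041 NAC transcription factor	321/399	12	88	0.0226	17	83	34	66	0.0047	26	74	0.0836
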