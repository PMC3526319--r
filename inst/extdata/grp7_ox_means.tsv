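primer_pair	agi	description	product_sizes	event_type	wt_col_small	wt_col_large	ox_col_small	ox_col_large	p_col	wt_c24_small	wt_c24_large	ox_c24_small	ox_c24_large	p_c24
#12	At1g72320	APUM23 pumilio RNA binding	141/150/215	alt_3ss	15	83	5	95	0.0002	23	74	8	92	0.0192
#19	At2g32320	tRNA His guanylyltransferase	202/273	alt_3ss	33	67	45	55	0.0047	31	69	39	61	0.0048
#36	At4g12790	ATP-binding family protein	212/338	alt_3ss	45	55	25	75	0.0029	46	54	25	75	0.0034
#49	At5g41150	UVH1 ultraviolet hypersensitive	293/346	alt_3ss	82	18	72	28	0.0003	92	8	84	16	0.0034
#59	At5g66010	RNA binding	105/182	alt_3ss	30	70	40	60	0.0261	38	62	59	41	0.0016
#242	At1g60850	ATRPAC42 RNA polymerase I subunit	111/122	alt_3ss	70	30	77	23	0.0311	73	27	79	21	0.0325
#254	At5g50240	L-isoaspartyl methyltransferase	192/201	alt_3ss	63	37	73	27	0.0282	64	36	73	27	0.0079
#273	At3g07810	hnRNP putative	126/173	alt_3ss	8	92	3	97	0.0094	10	90	4	96	0.0372
#288	At3g12570	FYD	159/188	alt_3ss	43	57	52	48	0.0148	39	61	53	47	0.0207
#295	At2g02390	ATGSTZ1 glutathione transferase	181/202	alt_3ss	88	12	69	31	0.0023	87	13	71	29	0.0016
#378	At3g62190	DNAJ heat shock domain protein	144/334	alt_3ss	89	11	99	1	0.0075	85	15	98	2	0.0032
#72	At2g04790	expressed protein	167/190	alt_5ss	68	32	53	47	0.0077	41	59	29	71	0.0027
#75	At2g36000	mTERF-related	150/254	alt_5ss	31	69	14	86	0.0009	40	60	17	83	0.0016
#87	At4g35450	AKR2 ankyrin repeat protein	305/350	alt_5ss	78	22	59	41	0.0052	72	28	57	43	0.0009
#90	At4g39260	AtGRP8 GR-RBP8	158/316	alt_5ss	94	6	23	77	0.0000	97	3	23	77	0.0004
#112	At1g09530	PIF3 phytochrome interacting factor	230/290	alt_5ss	88	12	59	41	0.0000	90	10	66	34	0.0033
#129	At2g40830	RHC1A RING-H2 finger	220/329	alt_5ss	91	9	59	41	0.0012	91	9	63	37	0.0037
#136	At3g07740	ADA2A adaptor	139/240	alt_5ss	100	0	46	54	0.0006	100	0	70	30	0.0063
#141	At3g51880	HMGB1 high mobility group	204/225	alt_5ss	92	8	79	21	0.0471	92	8	87	13	0.0003
#145	At3g17609	HYH Hy5-homolog	150/153/195/268	alt_5ss	32	68	54	46	0.0197	29	71	44	56	0.0275
#148	At1g76510	ARID/BRIGHT DNA-binding protein	189/212	alt_5ss	28	72	16	84	0.0073	37	63	25	75	0.0006
#149	At2g27230	transcription factor-related	208/246	alt_5ss	28	72	18	82	0.0177	34	66	22	78	0.0060
#189	At5g43270	SPL2 squamosa promoter binding	160/244	alt_5ss	87	13	63	37	0.0021	87	13	69	31	0.0044
#261	At4g10100	CNX7/SIR5	254/270	alt_5ss	58	42	46	54	0.0007	58	42	45	55	0.0028
#272	At3g23900	RRM-containing protein	118/125	alt_5ss	30	70	22	78	0.0008	30	70	23	77	0.0041
#285	At3g19840	FF/WW domain protein	171/207	alt_5ss	61	39	40	60	0.0004	65	35	43	57	0.0084
#322	At2g33480	ANAC041 NAC transcription factor	321/399	alt_5ss	17	83	34	66	0.0047	15	85	29	71	0.0025
#324	At5g43270	SPL2 squamosa promoter binding	186/270	alt_5ss	86	14	66	34	0.0046	95	5	66	34	0.0158
#343	At3g29160	AKIN11 protein kinase	159/307	alt_5ss	30	70	3	97	0.0008	45	55	2	98	0.0009
#181	At5g05550	transcription factor	210/308	exon_skipping	64	36	74	26	0.0143	59	41	75	25	0.0044
#196	At3g01150	PTB polypyrimidine tract binding	165/268	exon_skipping	91	9	97	3	0.0035	92	8	97	3	0.0071
#226	At4g24740	AFC2 LAMMER kinase	143/309	exon_skipping	19	81	47	53	0.0020	12	88	45	55	0.0004
#227	At4g24740	AFC2 LAMMER kinase	152/343	exon_skipping	30	70	73	27	0.0000	33	67	68	32	0.0005
#380	At5g08185	npcRNA78 MIR162a	103/168	exon_skipping	64	36	42	58	0.0044	83	17	75	25	0.0267
#327	At5g59950	Aly/REF export factor	226/422	intron_retention	84	16	50	50	0.0020	93	7	69	31	0.0091
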