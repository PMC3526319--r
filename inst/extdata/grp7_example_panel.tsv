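primer_pair	agi	description	product_sizes	event_type	relevant_sizes	designated_size	is_reference
#12	At1g72320	APUM23 pumilio RNA binding	141/150/215	alt_3ss	150/215	150	FALSE
#19	At2g32320	tRNA His guanylyltransferase	202/273	alt_3ss			FALSE
#36	At4g12790	ATP-binding family protein	212/338	alt_3ss			FALSE
#49	At5g41150	UVH1 ultraviolet hypersensitive	293/346	alt_3ss			FALSE
#59	At5g66010	RNA binding	105/182	alt_3ss			FALSE
#242	At1g60850	ATRPAC42 RNA polymerase I subunit	111/122	alt_3ss			FALSE
#254	At5g50240	L-isoaspartyl methyltransferase	192/201	alt_3ss			FALSE
#273	At3g07810	hnRNP putative	126/173	alt_3ss			FALSE
#288	At3g12570	FYD	159/188	alt_3ss			FALSE
#295	At2g02390	ATGSTZ1 glutathione transferase	181/202	alt_3ss			FALSE
#378	At3g62190	DNAJ heat shock domain protein	144/334	alt_3ss			FALSE
#72	At2g04790	expressed protein	167/190	alt_5ss			FALSE
#75	At2g36000	mTERF-related	150/254	alt_5ss			FALSE
#87	At4g35450	AKR2 ankyrin repeat protein	305/350	alt_5ss			FALSE
#90	At4g39260	AtGRP8 GR-RBP8	158/316	alt_5ss			FALSE
#112	At1g09530	PIF3 phytochrome interacting factor	230/290	alt_5ss			FALSE
#129	At2g40830	RHC1A RING-H2 finger	220/329	alt_5ss			FALSE
#136	At3g07740	ADA2A adaptor	139/240	alt_5ss			FALSE
#141	At3g51880	HMGB1 high mobility group	204/225	alt_5ss			FALSE
#145	At3g17609	HYH Hy5-homolog	150/153/195/268	alt_5ss			FALSE
#148	At1g76510	ARID/BRIGHT DNA-binding protein	189/212	alt_5ss			FALSE
#149	At2g27230	transcription factor-related	208/246	alt_5ss			FALSE
#189	At5g43270	SPL2 squamosa promoter binding	160/244	alt_5ss			FALSE
#261	At4g10100	CNX7/SIR5	254/270	alt_5ss			FALSE
#272	At3g23900	RRM-containing protein	118/125	alt_5ss			FALSE
#285	At3g19840	FF/WW domain protein	171/207	alt_5ss			FALSE
#322	At2g33480	ANAC041 NAC transcription factor	321/399	alt_5ss			FALSE
#324	At5g43270	SPL2 squamosa promoter binding	186/270	alt_5ss			FALSE
#343	At3g29160	AKIN11 protein kinase	159/307	alt_5ss			FALSE
#181	At5g05550	transcription factor	210/308	exon_skipping			FALSE
#196	At3g01150	PTB polypyrimidine tract binding	165/268	exon_skipping			FALSE
#226	At4g24740	AFC2 LAMMER kinase	143/309	exon_skipping			FALSE
#227	At4g24740	AFC2 LAMMER kinase	152/343	exon_skipping			FALSE
#380	At5g08185	npcRNA78 MIR162a	103/168	exon_skipping			FALSE
#327	At5g59950	Aly/REF export factor	226/422	intron_retention			FALSE
REF_ACTIN11	At3g12110	ACTIN11 reference (nominal product size)	180	reference			TRUE
REF_RPL12c	At2g37190	RPL12c reference (nominal product size)	210	reference			TRUE
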