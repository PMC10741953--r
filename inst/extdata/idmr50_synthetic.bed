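chrom	start	end	name	dmr_class	parental_origin
chr2	1034200	1034650	H19_IGF2	germline	paternal
chr3	1459800	1460350	DIRAS3_Ex2	germline	maternal
chr4	1066800	1067450	DIRAS3_TSS	germline	maternal
chr5	1187100	1187850	HTR5A_TSS	germline	maternal
chr6	1047500	1048350	IGF2_Ex9	secondary	paternal
chr7	1467800	1468250	PEG13	germline	maternal
chr8	1201400	1201950	GPR1_AS	germline	paternal
chr9	1392000	1392650	RB1	germline	maternal
chr10	1424200	1424950	PEG3	germline	maternal
chr11	1429300	1430150	WRB	germline	maternal
chr12	1264900	1265350	SNRPN_Int1	secondary	maternal
chr13	1424300	1424850	SNRPN_Int2	secondary	maternal
chr14	1081500	1082150	SNRPN_alt_TSS	secondary	maternal
chr15	1227000	1227750	ERLIN2_Int6	germline	maternal
chr16	1092000	1092850	MKRN3	secondary	maternal
chr17	1297700	1298150	ZNF331_2	germline	maternal
chr18	1237900	1238450	MEG3	germline	paternal
chr19	1371600	1372250	L3MBTL1	germline	maternal
chr20	1389800	1390550	NNAT_TSS	secondary	maternal
chr21	1146900	1147750	MCTS2P	germline	maternal
chr2	3132100	3132550	PPIEL	germline	maternal
chr3	3039200	3039750	ZNF597_TSS	secondary	paternal
chr4	3330100	3330750	MAGEL2	secondary	maternal
chr5	3238400	3239150	NDN_TSS	secondary	maternal
chr6	3344200	3345050	IGF1R_Int2	germline	maternal
chr7	3370400	3370850	PLAGL1	germline	maternal
chr8	3102700	3103250	KCNQ1OT1	germline	maternal
chr9	3118800	3119450	MEST	germline	maternal
chr10	3117400	3118150	GRB10	germline	maternal
chr11	3174000	3174850	PEG10	germline	maternal
chr12	3091700	3092150	NAP1L5	germline	maternal
chr13	3197300	3197850	INPP5F_v2	germline	maternal
chr14	3387300	3387950	FAM50B	germline	maternal
chr15	3052900	3053650	GNAS_XL	germline	maternal
chr16	3281800	3282650	GNAS_Ex1A	secondary	maternal
chr17	3301300	3301750	GNAS_AS1	germline	maternal
chr18	3345200	3345750	ZDBF2	germline	paternal
chr19	3482100	3482750	WDR27	germline	paternal
chr20	3181100	3181850	ZIM2	germline	maternal
chr21	3090200	3091050	RGMA	germline	maternal
chr2	5361800	5362250	SVOPL	germline	maternal
chr3	5494700	5495250	VTRNA2	germline	maternal
chr4	5349900	5350150	IGF2R	germline	maternal
chr5	5351100	5351350	IGF2_alt_TSS	germline	paternal
chr6	5296500	5296750	ZNF597_1	secondary	maternal
chr7	5472600	5472850	ZNF331_1	germline	maternal
chr8	5303300	5303550	CACNA1G	germline	maternal
chr9	5081200	5081450	SORD	secondary	maternal
chr10	5171100	5171350	HERC3	germline	maternal
chr11	5230500	5230750	PAX8_AS1	germline	maternal
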