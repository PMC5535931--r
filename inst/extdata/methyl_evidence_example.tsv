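protein_id	protein_prob	peptide_seq	peptide_prob	start_index	stop_index	mods	sample_id	n_mod_spectra	n_total_spectra	author_label
CBX3	0.999	WKDSDEADLVLAK	0.95	142	154	K2:me1	pooled_untreated	1	8	K142
CBX3	0.999	WKDSDEADLVLAK	0.95	142	154	K2:me1	pooled_treated	0	0	K142
EZH2	0.999	YSQADALKYVGIER	0.95	728	741	K8:me1	pooled_untreated	2	131	K735
EZH2	0.999	YSQADALKYVGIER	0.95	728	741	K8:me1	pooled_treated	2	106	K735
Histone_H1.2	0.999	KASGPPVSELITK	0.95	34	46	K1:me1	pooled_untreated	2	96	
Histone_H1.2	0.999	KASGPPVSELITK	0.95	34	46	K1:me1	pooled_treated	1	20	
Histone_H3.1	0.999	KSAPATGGVKPHR	0.95	28	41	K10:me1	pooled_untreated	0	18	
Histone_H3.1	0.999	KSAPATGGVKPHR	0.95	28	41	K10:me1	pooled_treated	1	6	
Histone_H3.1	0.999	EIAQDFKTDLR	0.95	74	84	K7:me1	pooled_untreated	1	18	
Histone_H3.1	0.999	EIAQDFKTDLR	0.95	74	84	K7:me1	pooled_treated	0	6	
MT1X	0.999	MDPNCSCSPVGSCAC-AGSCKCKECKCTSCK	0.95	1	30	K22:me1	pooled_untreated	1	1	
MT1X	0.999	MDPNCSCSPVGSCAC-AGSCKCKECKCTSCK	0.95	1	30	K22:me1	pooled_treated	0	0	
RL36L	0.999	KQSGYGGQTKPIFR	0.95	44	57	K10:me1	pooled_untreated	11	33	
RL36L	0.999	KQSGYGGQTKPIFR	0.95	44	57	K10:me1	pooled_treated	8	18	
SUZ12	0.999	APQKHGGGGGGGSGPSAGS-GGGGFGGSAAVAAATASGGK	0.95	2	40	K4:me1	pooled_untreated	2	154	K4
SUZ12	0.999	APQKHGGGGGGGSGPSAGS-GGGGFGGSAAVAAATASGGK	0.95	2	40	K4:me1	pooled_treated	0	138	K4
eEF1A1	0.999	GSFKYAWVLDK	0.95	52	62	K4:me2	pooled_untreated	7	59	K55
eEF1A1	0.999	GSFKYAWVLDK	0.95	52	62	K4:me2	pooled_treated	1	17	K55
eEF1A1	0.999	MDSTEPPYSQKR	0.95	155	166	K11:me2	pooled_untreated	0	59	K165
eEF1A1	0.999	MDSTEPPYSQKR	0.95	155	166	K11:me2	pooled_treated	1	17	K165
Histone_H3.1	0.999	KSAPATGGVKKPHR	0.95	28	41	K1:me2	pooled_untreated	1	18	
Histone_H3.1	0.999	KSAPATGGVKKPHR	0.95	28	41	K1:me2	pooled_treated	3	6	
Histone_H4	0.999	KVLRDNIQGITKPAIR	0.95	21	36	K1:me2	pooled_untreated	0	86	K20
Histone_H4	0.999	KVLRDNIQGITKPAIR	0.95	21	36	K1:me2	pooled_treated	1	23	K20
MYO1D	0.999	SKDTCIVISGESGAGKTEASK	0.95	93	113	K2:me2	pooled_untreated	0	0	
MYO1D	0.999	SKDTCIVISGESGAGKTEASK	0.95	93	113	K2:me2	pooled_treated	3	3	
RBP56	0.999	GPMTGSSGGDRGGFK	0.95	196	210	K15:me2	pooled_untreated	8	22	
RBP56	0.999	GPMTGSSGGDRGGFK	0.95	196	210	K15:me2	pooled_treated	0	6	
TR150	0.999	DSRPSQAAGDNQGDEAKEQ-TFSGGTSQDTK	0.95	186	215	K17:me2	pooled_untreated	7	32	
TR150	0.999	DSRPSQAAGDNQGDEAKEQ-TFSGGTSQDTK	0.95	186	215	K17:me2	pooled_treated	0	0	
ADT2	0.999	QYKGIIDCVVR	0.95	50	60	K3:me3	pooled_untreated	4	21	K52
ADT2	0.999	QYKGIIDCVVR	0.95	50	60	K3:me3	pooled_treated	1	13	K52
HNRPQ	0.999	GGNVGGKR	0.95	558	565	K7:me3	pooled_untreated	1	4	
HNRPQ	0.999	GGNVGGKR	0.95	558	565	K7:me3	pooled_treated	1	6	
MT1X	0.999	MDPNCSCSPVGSCACAGSC-KCKECKCTSCK	0.95	1	30	K20:me3;K25:me3;K30:me3	pooled_untreated	1	1	
MT1X	0.999	MDPNCSCSPVGSCACAGSC-KCKECKCTSCK	0.95	1	30	K20:me3;K25:me3;K30:me3	pooled_treated	0	0	
ALYREF	0.999	ADKMDMSLDDIIK	0.95	2	14	K3:me3	pooled_untreated	0	27	K4
ALYREF	0.999	ADKMDMSLDDIIK	0.95	2	14	K3:me3	pooled_treated	1	19	K4
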