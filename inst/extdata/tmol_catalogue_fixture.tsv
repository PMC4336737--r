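id	accession	gene_id	chromosome	family_branch	annotation	rpkm	rescue	gut_rank	active_site	s1	s2	homolog_mark	pseudogene	rpkm_ambiguous	fingerprint_ambiguous	curator_note
TmL13	KP303287	NA	NA	L	cathepsin L	19726.5	8496.6	NA	QCHN	GG	WMALA	0	0	0	0
TmL5	KP303279	NA	NA	L	cathepsin L	1356.6	572.7	NA	QCHN	GG	WMAFV	0	0	0	0
TmL11	KP303285	NA	NA	L	cathepsin L	1149.4	354.9	NA	QCHN	GG	EDGLT	0	0	0	0
TmL2	KP303276	NA	NA	L	cathepsin L	337.3	263.5	NA	QCHN	GG	LMALE	0	0	0	0
TmL4	KP303278	NA	NA	L	cathepsin L	326.9	168.9	NA	QCHN	GG	WMAFK	0	0	0	0
TmL1	KP303275	NA	NA	L	cathepsin L	162.2	113.9	NA	QCHN	GG	YMALQ	0	0	0	0
TmL30	KP303289	NA	NA	L	cathepsin L homolog	130.3	104.4	NA	ESHN	GG	SIALD	1	0	0	0	shares accession with TmL29
TmL29	KP303289	NA	NA	L	cathepsin L homolog	130.3	104.4	NA	QAHN	GG	LTALS	1	0	0	0	shares accession with TmL30
TmL3	KP303277	NA	NA	L	cathepsin L	62.1	31.3	NA	QCHN	GG	LMALE	0	0	0	0
TmL9	KP303283	NA	NA	L	cathepsin L	72.0	46.0	NA	QCHN	LE	MEIYY	0	0	0	0
TmL7	KP303281	NA	NA	L	cathepsin L	25.3	11.7	NA	QCHN	MQ	LDTFI	0	0	0	0
TmL6	KP303280	NA	NA	L	cathepsin L	15.8	5.8	NA	QCHN	GG	WMAFK	0	0	0	0
TmL8	KP303282	NA	NA	L	cathepsin L	5.7	3.7	NA	QCHN	MQ	LDTFR	0	0	0	0
TmL15	KP303288	NA	NA	L	cathepsin L	0.2	0.2	NA	QCHN	GG	WMAFQ	0	0	0	0
TmB33	KP303302	NA	NA	B	cathepsin B	2489.6	1160.4	NA	QCSN HH	GG	WPDGD	0	0	0	0	printed tetrad QCSN but classified typical active cathepsin B in text
TmB20	KP303293	NA	NA	B	cathepsin B-like	448.4	221.5	NA	QCHN	GG	YMNGY	0	0	0	0
TmB25	KP303297	NA	NA	B	cathepsin B-like	672.6	296.7	NA	QCHN	GG	WPSGN	0	0	0	0
TmB26	KP303298	NA	NA	B	cathepsin B-like	657.5	431.6	NA	QCHN	GG	SSSGN	0	0	0	0
TmB18	KP303291	NA	NA	B	cathepsin B	283.2	175.8	NA	QCHN HH	GG	YPSGD	0	0	0	0
TmB17	KP303290	NA	NA	B	cathepsin B	163.9	99.0	NA	QCHN HH	GG	FPAGE	0	0	0	0
TmB32	KP303301	NA	NA	B	cathepsin B homolog	77.9	37.5	NA	QSHN	GG	YLTGF	1	0	0	0
TmB23	KP303295	NA	NA	B	cathepsin B-like	48.8	29.3	NA	QCHN	GG	YVTGY	0	0	0	0
TmB19	KP303292	NA	NA	B	cathepsin B-like	34.2	24.9	NA	QCHN	GG	YIGGY	0	0	0	0
TmB27	KP303299	NA	NA	B	cathepsin B-like	26.5	13.9	NA	QCHN	GG	WMAFQ	0	0	0	0
TmB24	KP303296	NA	NA	B	cathepsin B-like	20.0	6.5	NA	QCHN	GG	APNGN	0	0	0	0
TmB28	KP303300	NA	NA	B	cathepsin B-like	4.0	2.2	NA	QCHN	SG	SSISH	0	0	0	0	atypical S1 Ser65 and His205
TmB22	KP303294	NA	NA	B	cathepsin B-like	1.2	0.7	NA	QCHN	GG	YMGGN	0	0	0	0
TmO12	KP303286	NA	NA	O	cathepsin O	38.4	22.2	NA	QCHN	GG	DVALE	0	0	0	0
TmF10	KP303284	NA	NA	F	cathepsin F	23.4	8.4	NA	QCHN	GG	LMALP	0	0	0	0
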