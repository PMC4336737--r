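id	accession	gene_id	chromosome	family_branch	annotation	rpkm	rescue	gut_rank	active_site	s1	s2	homolog_mark	pseudogene	rpkm_ambiguous	fingerprint_ambiguous	curator_note
NP_001164001	NP_001164001	LOC659441	10	L	cathepsin L	77228.22	NA	82	QCHN	GG	WMALA	0	0	1	0
NP_001164314	NP_001164314	LOC659502	10	L	cathepsin L	25848.86	NA	14	QCHN	GG	WMALA	0	0	1	0
XP_970644	XP_970644	LOC659226	10	L	cathepsin L	42.77	NA	7	QCHN	GG	LMALQ	0	0	1	0
XP_970773	XP_970773	LOC659367	10	L	cathepsin L homolog	35.06	NA	2	ESHN	GG	HATLS	1	0	1	0
XP_970951	XP_970951	LOC659565	10	L	cathepsin L	0.28	NA	2	QCHN	AG	LMAVQ	0	0	1	0
XP_971698	XP_971698	LOC660368	7	L	cathepsin L	2387.62	NA	44	QCHN	GG	WMAFK	0	0	1	0
XP_971867	XP_971867	LOC660551	7	L	cathepsin L	71.99	NA	1	QCHN	GG	WMAFK	0	0	1	0
XP_971752	XP_971752	LOC660428	7	L	cathepsin L	70.98	NA	1	QCHN	GG	YLSKR	0	0	1	0
XP_971975	XP_971975	LOC660669	7	L	cathepsin L	0.02	NA	2	QCHN	GG	WMALH	0	0	1	0
NC_007422	NC_007422	LOC660491	7	B	pseudogene	NA	NA	NA	-	NA	NA	0	1	0	0	questionable pseudogene; no RPKM calculable
XP_974298	XP_974298	LOC663145	3	B	cathepsin B	33142.15	NA	43	QCHN HH	GG	WPDGD	0	0	1	0
NP_001164205	NP_001164205	LOC663117	3	B	cathepsin B	31132.96	NA	46	QCHN HH	GG	MPSGG	0	0	1	0
XP_974244	XP_974244	LOC663090	3	B	cathepsin B	3248.71	NA	9	QCHN HH	GG	YMSGN	0	0	1	0
XP_974220	XP_974220	LOC663066	3	B	cathepsin B-like	379.91	NA	2	QCHN	GG	FPAGS	0	0	1	0
XP_966750	XP_966750	LOC655148	8	B	cathepsin B-like	443.27	NA	3	QCHN	GG	APHGY	0	0	1	0
XP_966663	XP_966663	LOC655077	8	B	cathepsin B-like	81.18	NA	3	QCHN	GG	YSSGN	0	0	1	0
XP_968689	XP_968689	LOC657117	8	B	cathepsin B homolog	57.60	NA	NA	QSTN	SG	YTAGS	1	0	0	0
XP_968767	XP_968767	LOC657203	8	B	cathepsin B-like	82.17	NA	3	QCHN	GG	YSGGS	0	0	1	0
XP_008196467	XP_008196467	LOC656957	8	B	cathepsin B-like	NA	NA	NA	QCHN	GG	YOYGE	0	0	0	1	listed as pseudogene in Tcas3; changed in Tcas4
XP_008196465	XP_008196465	LOC657038	8	B	cathepsin B-like	NA	NA	NA	QCHN	GG	YTTXE	0	0	0	1	listed as pseudogene in Tcas3; changed in Tcas4
NP_001164088	NP_001164088	LOC663234	7	L	cathepsin L	1309.16	NA	NA	QCHN	GG	EDALT	0	0	0	0	26-29-p; missed in original annotation
XP_969833	XP_969833	LOC658343	3	L	cathepsin L	0.02	NA	1	QCHN	GG	WIALH	0	0	1	0
XP_967834	XP_967834	LOC656198	7	B	cathepsin B homolog	28.64	NA	1	QSHN	GG	YLTGF	1	0	1	0	also XP_008195382
XP_970512	XP_970512	LOC659087	4	O	cathepsin O	11.99	NA	NA	QCHN	GG	DIALE	0	0	0	0
XP_973607	XP_973607	LOC662417	7	F	cathepsin F	2.32	NA	NA	QCHN	GG	LMALP	0	0	0	0	also XP_008195656
XP_001814509	XP_001814509	LOC100141668	1	K	cathepsin K	0	NA	1	QCHN	GG	SLSVY	0	0	1	0	chromosome 1 (X)
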