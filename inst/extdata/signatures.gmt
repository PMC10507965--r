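BINDEA_B_CELLS	surrogate cell-subset metagene	CD19	MS4A1	CD79A	CD79B	BLK	TCL1A	FCRL2
BINDEA_T_CELLS	surrogate cell-subset metagene	CD3D	CD3E	CD3G	CD2	CD6	TRAT1	ITM2A
BINDEA_T_HELPER	surrogate cell-subset metagene	CD4	ICOS	ITK	FYB1	ANP32E
BINDEA_TCM	surrogate cell-subset metagene	CCR7	SELL	IL7R	TCF7
BINDEA_TEM	surrogate cell-subset metagene	EOMES	CCR2	DPP4	TRA2A
BINDEA_TH1	surrogate cell-subset metagene	TBX21	IFNG	STAT4	IL12RB2	CTLA4	HAVCR2	LTA
BINDEA_TH2	surrogate cell-subset metagene	GATA3	IL4	IL5	IL13	CCR4	STAT6	PTGDR2
BINDEA_TH17	surrogate cell-subset metagene	RORC	IL17A	IL17RA	CCR6
BINDEA_TFH	surrogate cell-subset metagene	CXCL13	CXCR5	BCL6	ICOS	PDCD1
BINDEA_TREG	surrogate cell-subset metagene	FOXP3	IL2RA	IKZF2	TNFRSF18
BINDEA_CD8_T_CELLS	surrogate cell-subset metagene	CD8A	CD8B	GZMM	FLT3LG	PRR5
BINDEA_TGD	surrogate cell-subset metagene	TRGC1	TRDC	CD160	KIR2DL4
BINDEA_CYTOTOXIC_CELLS	surrogate cell-subset metagene	GZMA	GZMB	GZMH	PRF1	GNLY	KLRD1	NKG7	CTSW
BINDEA_NK_CELLS	surrogate cell-subset metagene	NCR1	KLRF1	KLRC1	XCL1	XCL2
BINDEA_NK_CD56DIM	surrogate cell-subset metagene	FCGR3A	SPON2	IL21R	KIR2DL1
BINDEA_NK_CD56BRIGHT	surrogate cell-subset metagene	NCAM1	KLRC3	SELL	XCL1
BINDEA_ANK_CD56DIM	surrogate cell-subset metagene	FCGR3A	GZMB	PRF1	KLRF1	SPON2
BINDEA_DC	surrogate cell-subset metagene	CD1C	CLEC10A	FCER1A	HLA-DQA1
BINDEA_IDC	surrogate cell-subset metagene	CD1A	CD1B	CD1E	MMP12	F13A1
BINDEA_ADC	surrogate cell-subset metagene	LAMP3	CCL19	CCL22	EBI3	CD83
BINDEA_PDC	surrogate cell-subset metagene	IL3RA	CLEC4C	LILRA4	PLD4
BINDEA_EOSINOPHILS	surrogate cell-subset metagene	IL5RA	CCR3	PRG2	EPX	SIGLEC8
BINDEA_MACROPHAGES	surrogate cell-subset metagene	CD68	CD163	MSR1	MRC1	SIGLEC1
BINDEA_MAST_CELLS	surrogate cell-subset metagene	TPSAB1	TPSB2	CPA3	MS4A2	KIT
BINDEA_NEUTROPHILS	surrogate cell-subset metagene	FCGR3B	CSF3R	CEACAM3	S100A12	FPR1
BINDEA_MONOCYTES	surrogate cell-subset metagene	CD14	FCN1	S100A8	S100A9	VCAN
BINDEA_NKT	surrogate cell-subset metagene	ZBTB16	SLAMF1	KLRB1	CD1D
BINDEA_APC	surrogate cell-subset metagene	HLA-DRA	HLA-DPA1	HLA-DPB1	CD74	CIITA
IFNA_ACTIVATION	surrogate pathway activation metagene	ISG15	MX1	MX2	OAS1	OAS2	OAS3	IFI6	IFI27	IFI44	IFI44L	IFIT1	IFIT3	RSAD2
IFNG_ACTIVATION	surrogate pathway activation metagene	IFNG	STAT1	IRF1	CXCL9	CXCL10	IDO1	GBP1	GBP4	HLA-DRA	PSMB9
TNFA_ACTIVATION	surrogate pathway activation metagene	TNF	NFKB1	NFKBIA	RELA	IL1B	IL6	CXCL8	TNFAIP3	CCL2	BIRC3
TP53_ACTIVATION	surrogate pathway activation metagene	CDKN1A	MDM2	BAX	GADD45A	BBC3	PMAIP1	SFN	SESN1	RRM2B	ZMAT3
APM	antigen processing and presentation machinery	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2	TAPBP	PSMB8	PSMB9	PSMB10	CALR	PDIA3
TIS	T cell-inflamed signature, 18 genes	CCL5	CD27	CD274	CD276	CD8A	CMKLR1	CXCL9	CXCR6	HLA-DQA1	HLA-DRB1	HLA-E	IDO1	LAG3	NKG7	PDCD1LG2	PSMB10	STAT1	TIGIT
TLS	tertiary lymphoid structure 12-chemokine signature	CCL2	CCL3	CCL4	CCL5	CCL8	CCL18	CCL19	CCL21	CXCL9	CXCL10	CXCL11	CXCL13
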