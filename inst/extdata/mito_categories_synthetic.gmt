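oxphos	synthetic mitochondrial functional category	NDUFA1	NDUFA2	NDUFB4	NDUFS1	NDUFV1	SDHA	SDHB	UQCRC1	UQCRC2	COX4I1	COX5A	COX6B1	ATP5F1A	ATP5F1B	ATP5MC1	ATP5PB
mitochondrial_carrier	synthetic mitochondrial functional category	SLC25A1	SLC25A3	SLC25A4	SLC25A5	SLC25A11	SLC25A12	SLC25A22
dynamics	synthetic mitochondrial functional category	MFN1	MFN2	OPA1	DNM1L	FIS1	MFF
matrix	synthetic mitochondrial functional category	CS	ACO2	IDH2	MDH2	FH	OGDH	PDHA1
inner_membrane	synthetic mitochondrial functional category	IMMT	TIMM23	TIMM50	OXA1L	LETM1
intermembrane_space	synthetic mitochondrial functional category	CYCS	HTRA2	CHCHD4	NDUFA8
glycolysis	synthetic cytosolic functional category	HK1	GPI1	PFKM	ALDOA	GAPDH	PGK1	ENO1	PKM
pentose_phosphate	synthetic cytosolic functional category	G6PDX	PGD	TKT	TALDO1
ros_defense	synthetic cytosolic functional category	SOD1	SOD2	CAT	GPX1	PRDX1	PRDX3	TXN1
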