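patient	kind	gene	gene3	hgvs	tissue_vaf	tissue_copies	plasma_vaf	plasma_copies	plasma_detected
1	INDEL	ERRFI1		c.1007_1016del	0.46		0.005		yes
1	SNV	TERT		-146T>C	0.35		0.009		yes
1	SNV	PALB2		c.1A>G	0.21		0.008		yes
1	SNV	TP53		c.743G>T	0.49		0.016		yes
1	CNV	CCND1		amplification		10		3.2	yes
1	CNV	FGF19		amplification		10		3.2	yes
1	CNV	FGF4		amplification		10		3.2	yes
1	CNV	FGF3		amplification		10		3.2	yes
2	INDEL	PIK3CA		c.328_330del	0.07		0.049		yes
2	SNV	CDH1		c.67C>T	0.10		0.085		yes
3	SNV	EGFR		c.2573T>G	0.34		0.324		yes
3	SNV	TP53		c.413C>T	0.46		0.065		yes
4	SNV	KRAS		c.38G>A	0.42				no
4	SNV	BAP1		c.783+2T>C	0.22				no
4	SNV	CDKN2A		c.151-1G>T	0.29				no
5	SNV	NRAS		c.183A>C	0.15				no
5	INDEL	APC		c.4280delC	0.60				no
5	SNV	ERBB3		c.695C>T	0.16				no
5	SNV	KDMA		c.641T>A	0.132				no
6	SNV	KRAS		c.35G>A	0.286		0.030		yes
6	SNV	RET		c.2410G>A	0.3244		0.0142		yes
6	SNV	IDH1		c.395G>T	0.2052		0.0098		yes
6	SNV	TP53		c.614A>G	0.4066		0.0224		yes
7	FUSION	EML4	ALK	EML4(6)-ALK(20)		2416	0.012		yes
8	SNV	CTNNB1		c.121A>G	0.422				no
8	FUSION	CD74	ROS1	CD74-ROS1		3895			no
9	SNV	TP53		c.814G>T	0.443		0.0055		yes
10	SNV	KRAS		c.35G>T	0.3225		0.0068		yes
10	SNV	PIK3CA		c.3139C>T	0.1269		0.0172		yes
10	SNV	MAP2K7		c.289C>T	0.1347		0.003		yes
10	SNV	TP53		c.734G>A	0.117		0.006		yes
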