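cancer_a	cancer_b	jaccard	category	variants
GC	Breast-AdenoCA	0.0064	***	16189|16278|7028|73
GC	Liver-HCC	0.0078	***	10810|11914|12705|14560|16111|16360|16519|16527
GC	Stomach-AdenoCA	0.0041	***	16311
GC	Lung-SCC	0.0051	**	11719
GC	Prost-AdenoCA	0.0118	**	11914|13789|1438|16111|16189|16278|16327|73
GC	Panc-AdenoCA	0.0086	**	11914|15043|16111|16129|16278|16327
GC	Kidney-RCC	0.0148	**	10810|11914|12705|14178|16111|16311|16527|9545
GC	ColoRect-AdenoCA	0.0072	**	13650|2706
GC	Eso-AdenoCA	0.0115	**	11914|16093|16111|16223|16311
GC	Lymph-CLL	0.0112	**	16327|3594
GC	Kidney-ChRCC	0.0113	**	16129|16189|8584
GC	Cervix-SCC	0.0101	*	11914
GC	Uterus-AdenoCA	0.0153	*	14560|16093|16189
GC	CNS-Medullo	0.0143	*	10873|16360|16519
GC	Ovary-AdenoCA	0.0094	*	11914|14560|16111|16189
GC	Breast-LobularCA	0.0111	*	489
GC	Head-SCC	0.0153	*	13650|16519|7028
GC	Thy-AdenoCA	0.0143	*	16129|16223|3666
GC	SoftTissue-Leiomyo	0.0121	*	16527
GC	CNS-Oligo	0.0111	*	16223
GC	Panc-Endocrine	0.0092	*	16527|3666
GC	Lymph-BNHL	0.0164	*	11914|14560|16189|3666
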