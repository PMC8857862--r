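position	region	somatic
73	D-loop	1
489	D-loop	1
1438	MT-RNR1	0
2706	MT-RNR2	0
3594	MT-ND1	1
3666	MT-ND1	1
7028	MT-CO1	0
8584	MT-ATP6	0
9545	MT-CO3	0
10810	MT-ND4	1
10873	MT-ND4	1
11719	MT-ND4	0
11914	MT-ND4	0
12705	MT-ND5	0
13650	MT-ND5	1
13789	MT-ND5	1
14178	MT-ND6	0
14560	MT-ND6	0
15043	MT-CYB	0
16093	D-loop	1
16111	D-loop	0
16129	D-loop	0
16189	D-loop	1
16223	D-loop	0
16278	D-loop	0
16311	D-loop	0
16327	D-loop	0
16360	D-loop	1
16519	D-loop	0
16527	D-loop	0
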