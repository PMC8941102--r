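node	clade	calibration	family	tL	tU	pL	pU	p	c	strategies
1	UTC_plus_Chlorodendrophyceae	root	uniform	10.00	18.91	1e-300	0.025	NA	NA	1,2,3
2	Trebouxiophyceae	Botryococcus_stem	cauchy_min	2.9875	NA	1e-300	NA	0.1	1	1,2,3
3	Chlorophyceae	Scenedesmus_stem	cauchy_min	1.25	NA	1e-300	NA	0.1	1	1,2,3
4	Ulvophyceae	Bryopsidales_stem	cauchy_min	4.523	NA	1e-300	NA	0.1	1	1,2,3
5	Ulvophyceae	Bryopsidales_crown	uniform	4.25	5.33	0.025	0.025	NA	NA	1,2,3
6-1	Ulvophyceae	Cladophorales_stem	cauchy_min	10.00	NA	1e-300	NA	0.1	1	1
6-2	Ulvophyceae	Ulvophyceae_ss_stem	cauchy_min	10.00	NA	1e-300	NA	0.1	1	2
7	Ulvophyceae	Dasycladales_stem	cauchy_min	4.438	NA	1e-300	NA	0.1	1	1,2,3
8	Ulvophyceae	Dasycladales_crown	uniform	4.07	5.17	0.025	0.025	NA	NA	1,2,3
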