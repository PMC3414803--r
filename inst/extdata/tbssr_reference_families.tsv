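# Reference TBSSR family table: per-family sizes, MGE-type member counts and
# manually assigned type / catalytic-motif labels for a published curated
# corpus of 1,309 tyrosine recombinases (families of 4 or more members).
# NA marks counts that were not determined in the source table.
famint	mge_type_label	n_prot	n_gi	n_phage	n_prophage	n_plasmid	motif_label
0	intG	210	153	10	38	9	no obvious one
1	RIT(A)	64	NA	0	3	33	RH-Y
2	RIT(C)	63	NA	0	0	34	RH-Y
3	mix	61	0	5	15	41	RK-Y
4	mix	58	0	27	29	2	RH-Y
5	RIT(B)	54	NA	0	0	27	RH-Y
6	(pro)phage	52	0	16	36	0	RH/R-Y
7	(pro)phage	47	0	18	29	0	RHT/S-Y
8	IntI	44	0	0	1	43	RH-Y
9	plasmid	43	0	0	0	43	RHS-Y
10	plasmid	39	0	0	0	39	RH-Y
11	plasmid	37	0	0	0	37	R-Y
12	(pro)phage	35	0	8	27	0	RHT-Y
13	(pro)phage	30	0	11	19	0	RH-Y
14	Tn4371	25	13	0	5	7	RH-Y
15	(pro)phage	22	0	3	19	0	RSL or RLY-Y
16	(pro)phage	22	1	12	9	0	RHT-Y
17	(pro)phage	20	0	13	7	0	RHS-Y
18	plasmid	16	0	0	0	16	RSG-Y
19	BIM(A)	14	NA	0	0	8	RH-Y
20	mix	14	0	1	9	4	R-Y
21	prophage, plasmid	12	0	0	3	9	RRT-Y
22	plasmid	11	0	0	0	11	RRTF-Y
23	plasmid	11	0	0	0	11	R-Y
24	prophage	10	0	0	10	0	RK-Y
25	(pro)phage	10	0	4	6	0	RH-Y
26	(pro)phage	9	0	3	6	0	RH-Y
27	plasmid	9	0	0	0	9	RHT-Y
28	phage, plasmid	9	0	0	4	5	RH-Y
29	mix	9	0	1	7	1	R-Y
30	plasmid	9	0	0	0	9	R-Y
31	plasmid	8	0	0	0	8	RH-Y
32	plasmid	8	0	0	0	8	R-Y
33	plasmid	8	0	0	0	8	R-Y
34	plasmid	8	0	0	0	8	RAT-Y
35	(pro)phage	8	0	1	7	0	No R at expected distance from Y
36	plasmid	8	0	0	0	8	RH-Y, partner 41, 90
37	mix	7	0	0	6	1	RH-Y
38	plasmid	7	0	0	0	7	RR-Y
39	plasmid	7	0	0	0	7	RH-Y
40	plasmid	7	0	0	0	7	RHS-Y
41	plasmid	7	0	0	0	7	RR-Y
42	mix	6	0	0	1	5	RH-Y
43	plasmid	6	0	0	0	6	RR-Y
44	plasmid	6	0	0	0	6	RH-Y
46	plasmid	6	0	0	0	6	RHT-Y
47	mix	5	0	3	1	1	RH-Y
48	mix	5	0	3	0	2	R-Y
49	plasmid	5	0	0	0	5	RRTAL-Y
50	(pro)phage	5	0	4	1	0	RHT-Y
51	(pro)phage	4	0	3	1	0	RHT-Y
52	prophage	4	0	0	4	0	RK-Y
53	plasmid	4	0	0	0	4	RH-Y, partner 62, one has no partner
54	plasmid	4	0	0	0	4	RHTF-Y
55	plasmid	4	0	0	0	4	R-Y
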