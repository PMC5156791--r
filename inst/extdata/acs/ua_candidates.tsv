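# Published candidate biomarker miRNAs for unstable angina (UA):
# per-miRNA target count N, novel out-degree NOD, TF-target count, and the
# number of significantly enriched pathways the miRNA regulates.
mirna	n_targets	nod	tf_targets	pathways
miR-197	151	32	24	2
miR-125b	109	30	20	4
miR-590-3p	255	18	44	2
miR-22*	158	16	32	0
miR-204	198	15	40	2
miR-34a	80	14	15	6
miR-486-3p	152	13	23	2
let-7g	199	13	34	13
miR-346	31	13	5	4
miR-340	256	11	37	1
miR-340*	256	11	37	1
miR-196b	165	11	27	5
miR-145	55	11	11	3
miR-324-3p	84	10	12	1
miR-126	34	10	5	13
miR-106b	376	9	61	1
miR-885-5p	89	9	14	0
miR-132	46	8	7	0
miR-17	80	8	13	5
miR-597	76	8	12	2
miR-142-3p	87	8	18	1
miR-25	260	7	40	0
miR-590-5p	112	7	23	0
miR-324-5p	78	7	18	2
miR-93	394	6	68	0
miR-618	112	6	17	0
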