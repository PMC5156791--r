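# Published candidate biomarker miRNAs for acute myocardial infarction (AMI):
# per-miRNA target count N, novel out-degree NOD, TF-target count, and the
# number of significantly enriched pathways the miRNA regulates.
mirna	n_targets	nod	tf_targets	pathways
miR-155	185	64	39	16
miR-30e	356	32	56	5
miR-98	329	24	62	2
miR-23b	211	18	34	5
miR-204	198	15	40	10
miR-34a	80	14	15	5
let-7g	199	13	34	24
miR-576-3p	133	13	23	0
miR-346	31	13	5	5
miR-454	298	13	43	0
miR-532-3p	112	12	18	5
miR-145	55	11	11	8
miR-340*	256	11	37	3
miR-126	34	10	5	29
miR-621	65	10	13	9
miR-142-3p	87	8	18	3
miR-31	34	7	8	5
miR-600	127	7	23	1
miR-491-3p	119	6	21	0
miR-603	149	6	32	2
miR-93	394	6	68	0
miR-934	72	5	12	0
miR-27a	50	5	15	3
miR-548b-3p	103	5	18	0
miR-101	69	4	18	4
miR-128	22	4	4	0
miR-95	69	4	10	0
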