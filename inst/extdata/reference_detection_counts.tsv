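biotype	median_per_cell	min_per_cell	max_per_cell	detected_total	annotated_total	detected_total_text
coding	8746	1216	13862	20431	20447	20436
antisense	18	0	45	99	99	NA
lincRNA	33	4	94	169	169	NA
rRNA	6	6	21	22	22	NA
snoRNA	28	4	72	338	345	NA
pseudogene	132	24	644	1546	1590	NA
snRNA	6	0	59	126	130	NA
tRNA	5	0	112	571	637	NA
unknown_ncRNA	223	37	1022	6972	7687	NA
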