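signal	subgenome	I	II	III	IV	V	VI	VII	total
supportive	Av	54	120	55	97	118	198	90	732
supportive	Bi	44	117	78	93	91	175	102	700
supportive	B1	60	104	43	67	84	120	72	550
supportive	B2	61	104	46	91	86	113	59	560
clustered_introgression	Av	0	0	0	0	0	0	0	0
clustered_introgression	Bi	2	4	4	0	11	2	5	28
clustered_introgression	B1	10	7	16	15	2	19	25	94
clustered_introgression	B2	6	0	0	0	4	3	17	30
clusters	Av	0	0	0	0	0	0	0	0
clusters	Bi	1	2	2	0	4	1	1	11
clusters	B1	2	2	5	3	1	8	5	26
clusters	B2	3	0	0	0	2	1	5	11
isolated_introgression	Av	2	4	3	6	4	8	7	34
isolated_introgression	Bi	6	4	7	6	11	8	3	45
isolated_introgression	B1	4	7	5	6	3	17	12	54
isolated_introgression	B2	5	5	7	9	5	10	9	50
outgroup_homoplasy	Av	2	6	3	6	6	10	18	51
outgroup_homoplasy	Bi	1	2	4	3	3	10	7	30
outgroup_homoplasy	B1	2	7	5	5	3	14	16	52
outgroup_homoplasy	B2	8	6	5	2	10	19	13	63
support_homoplasy	Av	1	5	3	6	5	7	4	31
support_homoplasy	Bi	1	6	1	3	4	8	8	31
support_homoplasy	B1	3	9	3	8	6	16	10	55
support_homoplasy	B2	2	10	6	5	10	11	13	57
informative_regions	All	160	298	185	230	255	421	264	1813
informative_markers	All	317	645	367	483	568	902	536	3818
total_markers	All	540	1152	627	784	905	1517	956	6481
missing_pct	All	64.5	64.5	64.5	63.2	64.1	63.9	64.6	64.2
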