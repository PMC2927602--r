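pdb_id	chain_first	chain_second	description	n_first	n_second	n_both	interface_area	interface_size	semi_first	semi_second	interface_type	obligate_class
1a03	A	B	calcium-binding protein	90	90	180	3071	82	37	45	I	obligate
1gdh	A	B	oxidoreductase	320	320	640	6254	148	74	74	I	obligate
1a05	A	B	oxidoreductase	357	357	714	5258	125	62	63	I	obligate
1ag1	O	T	isomerase	249	249	498	3025	75	37	38	I	obligate
1hii	A	B	hydrolase	99	99	198	3436	83	41	42	I	obligate
1mdi	A	B	electron transport/peptide	105	13	118	1340	34	24	10	I	non-obligate
2gsa	A	B	chlorophyll biosynthesis	427	427	854	9178	233	118	115	I	obligate
1ger	A	B	oxidoreductase	448	448	896	6777	172	86	86	I	obligate
1azy	A	B	glicosyltransferase	440	440	880	1744	42	21	21	II	non-biological
1a0a	A	B	transcription factor	63	63	126	1860	44	22	22	II	obligate
1mv4	A	B	de novo protein	37	37	74	1833	43	21	22	II	obligate
1a93	A	B	leucine zipper	32	32	64	1565	34	17	17	II	non-obligate
1a15	A	B	chemokine	67	67	124	1480	38	18	20	II	obligate
1q6a	A	B	circadian clock protein	107	107	214	1810	46	23	23	II	non-obligate
2fhw	B	A	signaling protein	27	24	51	1153	29	15	14	III	obligate
1jm7	A	B	antitumor	103	97	200	2769	72	39	33	III	obligate
1tmz	A	B	tropomyosin	32	32	64	1586	35	17	18	III	obligate
1an2	A	C	DNA-binding protein	86	86	172	2571	64	32	32	III	obligate
2sic	E	I	proteinase/inhibitor	275	107	382	1617	45	31	14	III	non-obligate
1lfa	A	B	cell adhesion	183	183	365	628	21	10	11	III	non-biological
1shc	A	B	signal transduction/peptide	195	11	206	1456	34	25	9	III	non-obligate
2a93	A	B	leucine zipper	32	32	64	1568	34	16	18	III	non-obligate
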