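symbol	description	probe_id	probe_target	chr	mb	qtl_chr	qtl_mb	locus	max_lrs	mean_expr
Tshz2	teashirt zinc finger family member 2	ILMN_1246021	intron 2	2	169.6	2	169.58	rs13476910	17.67	7.75
Tshz2	teashirt zinc finger family member 2	ILMN_1256408	exon 4	2	169.71	2	168.79	rs6160839	17.9	8.01
Tshz2	teashirt zinc finger family member 2	ILMN_1243934	putative intergenic	2	169.74	2	168.79	rs6160839	62.16	8.46
Dok5	docking protein 5	ILMN_2615070	exon 8	2	170.7	2	173.43	rs3664044	17.35	7.95
Rae1	RAE1 RNA export 1	ILMN_2713130	3' UTR	2	172.84	2	172.56	rs3668691	45.41	10.87
RP23-330D3.5	novel KRAB box and zinc finger, C2H2 type domain containing protein	ILMN_2536053	intron 4	2	174.89	2	172.56	rs3668691	15.55	8.14
Cdh4	cadherin 4	ILMN_1255939	exon 16	2	179.63	2	179.26	rs6187766	30.81	7.88
AW120700		ILMN_1260036	putative intergenic	2	179.63	2	179.26	rs6187766	48.19	11.07
Ogfr	opioid growth factor receptor	ILMN_1250450	3' UTR	2	180.33	2	180.83	rs6305540	34.82	11.04
Bhlhb4	basic helix-loop-helix domain containing, class B4	ILMN_1227215	distal 3' UTR	2	180.51	2	179.7	rs3703298	31.4	8.44
Kcnq2	potassium voltage-gated channel, subfamily Q, member 2	ILMN_1241017	intron 8	2	180.84	2	180.83	rs6305540	76.68	7.73
6330503H08Rik		ILMN_2564036	putative intergenic	2	180.87	2	180.83	rs6305540	23.9	8.18
2700038C09Rik	RIKEN cDNA 2700038C09 gene	ILMN_2590015	5' UTR	2	180.92	2	180.83	rs6305540	16.9	9.73
Rtel1	regulator of telomere elongation helicase 1	ILMN_2641946	3' UTR	2	181.09	2	180.83	rs6305540	68.62	8.6
Arfrp1	ADP-ribosylation factor related protein 1	ILMN_2631745	exon 6	2	181.1	2	180.83	rs6305540	16.15	11.23
Dnajc5	DnaJ (Hsp40) homolog, subfamily C, member 5	ILMN_2501026	putative intergenic	2	181.29	2	180.83	rs6305540	117.47	14.35
Tcea2	transcription elongation factor A (SII), 2	ILMN_2777609	3' UTR	2	181.42	2	180.83	rs6305540	70.53	10.58
2810410D24Rik	RIKEN cDNA 2810410D24 gene	ILMN_2493144	putative intergenic	2	181.6	2	179.7	rs3703298	22.87	7.77
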