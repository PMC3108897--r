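symbol	description	probe_id	probe_target	chr	mb	qtl_chr	qtl_mb	locus	max_lrs	mean_expr
Phf5a	PHD finger protein 5A	ILMN_1251761	3' UTR	15	81.7	15	82.3	D15Mit189	32.6	13.6
Aco2	aconitase 2, mitochondrial	ILMN_1235786	exon 19	15	81.7	15	79.7	rs4230879	15.6	12.4
Polr3h	polymerase (RNA) III (DNA directed) polypeptide H	ILMN_1218993	3' UTR	15	81.7	15	79.5	rs4230869	21	10.9
Pmm1	phosphomannomutase 1	ILMN_2611027	exon 7	15	81.8	15	82.3	D15Mit189	30.4	12.3
Pmm1	phosphomannomutase 1	ILMN_1223710	5' UTR	15	81.8	15	83.9	rs13482681	16.8	10.3
Xrcc6	X-ray repair complementing defective repair in Chinese hamster cells 6	ILMN_1247814	exon 13	15	81.9	15	79.7	rs4230879	18.6	9.6
Xrcc6	X-ray repair complementing defective repair in Chinese hamster cells 6	ILMN_2862619	3' UTR	15	81.9	15	79.5	rs4230869	42.6	12
Serhl	serine hydrolase-like	ILMN_2614351	exon 11	15	82.9	15	82.9	rs13482677	130.8	7.7
Mcat	malonyl CoA:ACP acyltransferase (mitochondrial)	ILMN_2619455	3' UTR	15	83.4	15	82.9	rs13482677	97.8	10.6
Mcat	malonyl CoA:ACP acyltransferase (mitochondrial)	ILMN_2927635	exon 3	15	83.4	15	83.9	rs13482681	76	7.6
Phf21b	PHD finger protein 21B	ILMN_1229266	3' UTR	15	84.6	15	87.9	rs3707587	28.9	11.6
Fbln1	fibulin 1	ILMN_2602770	3' UTR	15	85.1	15	82.9	rs13482677	24.1	7.6
2210021J22Rik	RIKEN cDNA 2210021J22 gene	ILMN_2781118	exon 4	15	85.6	15	83.9	rs13482681	36.4	8.1
Tbc1d22a	TBC1 domain family, member 22a	ILMN_2767791	3' UTR	15	86.3	15	85.5	rs13482686	30.3	11.4
Zbed4	zinc finger, BED domain containing 4	ILMN_2418222	3' UTR	15	88.6	15	87.3	rs6405854	17.6	9.4
Arsa	arylsulfatase A	ILMN_1225552	3' UTR	15	89.3	15	88.3	rs13482695	42	10
Rabl2a	RAB, member of RAS oncogene family-like 2A	ILMN_2593578	3' UTR	15	89.4	15	88.3	rs13482695	36.6	12.2
Rabl2a	RAB, member of RAS oncogene family-like 2A	ILMN_2742942	exon 7	15	89.4	15	89.4	rs4230970	69.9	7.6
Cpne8	copine VIII	ILMN_3151149	intron 2	15	90.5	15	87.9	rs3707587	22.7	9.8
Kif21a	kinesin family member 21A	ILMN_2718716	exon 33	15	90.8	15	89.4	rs4230970	25.1	12.3
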