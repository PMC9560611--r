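##fileformat=VCFv4.2
##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p | etc">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	1010	.	A	G	45	.	.
chr1	1020	.	C	T	45	.	.
chr1	1030	.	A	G	45	.	.
chr1	1040	.	C	T	45	.	.
chr1	1050	.	A	G	25	.	.
chr1	1060	.	C	T	45	.	.
chr1	1070	.	A	G	45	.	.
chr1	1080	.	C	T	45	.	.
chr1	1090	.	A	G	45	.	.
chr1	1100	.	C	T	25	.	.
chr1	1110	.	A	G	45	.	.
chr1	1120	.	C	T	45	.	.
chr1	1130	.	A	G	45	.	.
chr1	1140	.	C	T	45	.	.
chr1	1150	.	A	G	25	.	.
chr1	1160	.	C	T	45	.	.
chr1	1170	.	A	G	45	.	.
chr1	1180	.	C	T	45	.	.
chr1	1190	.	A	G	45	.	.
chr1	1200	.	C	T	25	.	.
chr1	1210	.	A	G	45	.	ANN=G|missense_variant|MODERATE|TP53|GENE1|transcript|TX1|protein_coding|1/1|c.1A>G|p.Tyr205Cys|||||
chr1	1220	.	C	T	45	.	ANN=T|missense_variant|MODERATE|ERBB2|GENE2|transcript|TX2|protein_coding|1/1|c.2T>C|p.Leu755Ser|||||
chr1	1230	.	A	G	45	.	ANN=G|missense_variant|MODERATE|KRAS|GENE3|transcript|TX3|protein_coding|1/1|c.3G>A|p.Gly12Asp|||||
chr1	1240	.	C	T	45	.	ANN=T|splice_region_variant&intron_variant|LOW|APC|GENE4|transcript|TX4|protein_coding|1/1|c.4|||||
chr1	1250	.	A	G	25	.	.
chr1	1260	.	C	T	45	.	.
chr1	1270	.	A	G	45	.	.
chr1	1280	.	C	T	45	.	.
chr1	1290	.	A	G	45	.	.
chr1	1300	.	C	T	25	.	.
chr1	1310	.	A	G	45	.	.
chr1	1320	.	C	T	45	.	.
chr1	1330	.	A	G	45	.	.
chr1	1340	.	C	T	45	.	.
chr1	1350	.	A	G	25	.	.
chr1	1360	.	C	T	45	.	.
chr1	1370	.	A	G	45	.	.
chr1	1380	.	C	T	45	.	.
chr1	1390	.	A	G	45	.	.
chr1	1400	.	C	T	25	.	.
chr1	1410	.	A	G	45	.	.
chr1	1420	.	C	T	45	.	.
chr1	1430	.	A	G	45	.	.
chr1	1440	.	C	T	45	.	.
chr1	1450	.	A	G	25	.	.
chr1	1460	.	C	T	45	.	.
chr1	1470	.	A	G	45	.	.
chr1	1480	.	C	T	45	.	.
chr1	1490	.	A	G	45	.	.
chr1	1500	.	C	T	25	.	.
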