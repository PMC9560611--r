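##fileformat=VCFv4.2
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	1010	.	A	G	.	.	.
chr1	1020	.	C	T	.	.	.
chr1	1030	.	A	G	.	.	.
chr1	1100	.	C	T	.	.	.
chr1	1110	.	A	G	.	.	.
chr1	1120	.	C	T	.	.	.
chr1	1410	.	A	G	.	.	.
chr1	1040	.	C	G	.	.	.
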