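##fileformat=VCFv4.2
##source=hand-written synthetic fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ecoA	ecoB	ecoC
1	1200	snp_a	A	T	.	PASS	.	GT	0	1	0
1	5600	snp_b	C	G	.	PASS	.	GT	1/1	0/0	0/1
1	9100	snp_c	G	A	.	PASS	.	GT	1	.	0
2	500	snp_multi	A	T,G	.	PASS	.	GT	0	1	2
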