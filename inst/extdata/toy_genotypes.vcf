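##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	bird1	bird2	bird3	bird4
1	100	m1	A	G	.	PASS	.	GT	0/0	0/1	1/1	0/1
1	200	m2	A	C	.	PASS	.	GT	0/0	./.	./.	1/1
2	150	m3	T	A	.	PASS	.	GT	0/0	0/0	0/0	0/0
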