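##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence term">
##INFO=<ID=CARRIERS,Number=1,Type=Integer,Description="Internal carrier count">
##INFO=<ID=PP2,Number=1,Type=Float,Description="PolyPhen2 score">
##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT score">
##INFO=<ID=CONDEL,Number=1,Type=Float,Description="Condel score">
##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD Phred score">
##INFO=<ID=KGP,Number=1,Type=Float,Description="Reference AF, set kgp">
##INFO=<ID=KP,Number=0,Type=Flag,Description="Known pathogenic">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	1234	.	C	T	.	PASS	GENE=DOM1;CSQCLASS=stop_gained;CARRIERS=1	GT	0/1	0/0	0/0
1	2345	.	G	GA	.	PASS	GENE=REC1;CSQCLASS=frameshift_variant;CARRIERS=2	GT	0/0	1/1	0/0
1	3456	.	A	G	.	PASS	GENE=DOM1;CSQCLASS=missense_variant;CARRIERS=1;PP2=0.95;SIFT=0.02;CONDEL=0.6;CADD=27.5;KP	GT	0/0	0/0	0/1
X	4567	.	T	C	.	PASS	GENE=XL1;CSQCLASS=splice_donor_variant;CARRIERS=1	GT	1	0/0	0/0
1	5678	.	C	A	.	PASS	GENE=CAND1;CSQCLASS=synonymous_variant;CARRIERS=3;KGP=0.004	GT	0/1	0/1	0/0
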