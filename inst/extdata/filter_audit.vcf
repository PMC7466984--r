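##fileformat=VCFv4.2
##source=methmut synthetic filter-audit fixture (hand-written)
##note=20 records exercising every removal rule of the rare-SNP filter
##note=autosomes for this fixture are chr1,chr2
##expected=structural:2 indel:3 multiallelic:2 non_autosomal:2
##expected=frequency_unknown:1 allele_frequency:3 quality:3 retained:4
##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">
##INFO=<ID=AC,Number=A,Type=Integer,Description="Allele count">
##INFO=<ID=AN,Number=1,Type=Integer,Description="Allele number">
##contig=<ID=chr1,length=100000>
##contig=<ID=chr2,length=100000>
##contig=<ID=chrX,length=100000>
##contig=<ID=chrY,length=100000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	101	.	C	T	100	PASS	AF=0.0005
chr1	205	.	G	A	100	PASS	AF=0.0002
chr2	310	.	T	G	100	PASS	AC=1;AN=5008
chr2	422	.	A	C	100	PASS	AF=0.00099
chr1	530	.	C	<DEL>	100	PASS	AF=0.0005
chr1	640	.	G	<INS>	100	PASS	AF=0.0005
chr1	751	.	A	AT	100	PASS	AF=0.0005
chr1	860	.	CT	C	100	PASS	AF=0.0005
chr1	977	.	G	GGG	100	PASS	AF=0.0005
chr2	1080	.	C	G,T	100	PASS	AF=0.0004,0.0001
chr2	1190	.	A	C,G	100	PASS	AF=0.0002,0.0003
chrX	1201	.	C	T	100	PASS	AF=0.0005
chrY	1315	.	G	A	100	PASS	AF=0.0005
chr1	1420	.	T	A	100	PASS	.
chr1	1533	.	C	T	100	PASS	AF=0.002
chr2	1644	.	G	C	100	PASS	AF=0.001
chr2	1755	.	A	G	100	PASS	AF=0.5
chr1	1868	.	C	A	90	PASS	AF=0.0005
chr1	1979	.	T	C	99.9	PASS	AF=0.0005
chr2	2087	.	G	T	.	PASS	AF=0.0005
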