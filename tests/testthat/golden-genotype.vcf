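##fileformat=VCFv4.2
##source=panotype
##contig=<ID=chr1,length=12000>
##INFO=<ID=BUBBLE,Number=1,Type=Integer,Description="Pangenome bubble id">
##INFO=<ID=NALL,Number=1,Type=Integer,Description="Number of bubble alleles">
##INFO=<ID=COMPLEX,Number=0,Type=Flag,Description="Bubble has more than two alleles">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10-scaled genotype likelihoods">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE
chr1	954	chr1:954:A>T	A	T	.	PASS	BUBBLE=1;NALL=3;COMPLEX	GT:GQ:GL	0/0:10000:0.0000,-141.0059,-300.0000
chr1	968	chr1:968:A>G	A	G	.	PASS	BUBBLE=1;NALL=3;COMPLEX	GT:GQ:GL	1/1:10000:-300.0000,-141.0059,0.0000
chr1	1091	chr1:1091:TAAGTGCGCAATTAGTCATGTATCTAAAGCTCTAATTTGAGGCTCTAGAAGCGCATAGACAGAAGGAATTATAACCAATTTGGCGAGCGTTACTTGTTTCGAT>T	TAAGTGCGCAATTAGTCATGTATCTAAAGCTCTAATTTGAGGCTCTAGAAGCGCATAGACAGAAGGAATTATAACCAATTTGGCGAGCGTTACTTGTTTCGAT	T	.	PASS	BUBBLE=2;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-300.0000,0.0000
chr1	1247	chr1:1247:G>T	G	T	.	PASS	BUBBLE=3;NALL=2	GT:GQ:GL	1/1:10000:-276.6947,-67.7247,0.0000
chr1	1750	chr1:1750:TAGGGCGATTGGCTTGGTAAT>T	TAGGGCGATTGGCTTGGTAAT	T	.	PASS	BUBBLE=4;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-114.8575,0.0000
chr1	1818	chr1:1818:T>A	T	A	.	PASS	BUBBLE=5;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-117.1734,-300.0000
chr1	1871	chr1:1871:G>A	G	A	.	PASS	BUBBLE=6;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-132.9889,-300.0000
chr1	2571	chr1:2571:T>A	T	A	.	PASS	BUBBLE=7;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-216.3798,0.0000
chr1	2602	chr1:2602:T>G	T	G	.	PASS	BUBBLE=7;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-216.3798,0.0000
chr1	2915	chr1:2915:G>T	G	T	.	PASS	BUBBLE=8;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-132.8120,0.0000
chr1	3168	chr1:3168:G>C	G	C	.	PASS	BUBBLE=9;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-152.1064,-300.0000
chr1	3224	chr1:3224:T>A	T	A	.	PASS	BUBBLE=10;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-124.6322,0.0000
chr1	3339	chr1:3339:T>C	T	C	.	PASS	BUBBLE=11;NALL=2	GT:GQ:GL	0/1:33:-144.9879,-0.0002,-3.3122
chr1	4141	chr1:4141:A>G	A	G	.	PASS	BUBBLE=12;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-123.5903,-300.0000
chr1	4783	chr1:4783:T>C	T	C	.	PASS	BUBBLE=13;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-145.8580,-300.0000
chr1	5220	chr1:5220:G>C	G	C	.	PASS	BUBBLE=14;NALL=3;COMPLEX	GT:GQ:GL	1/1:10000:-285.5492,-71.1575,0.0000
chr1	5220	chr1:5220:G>T	G	T	.	PASS	BUBBLE=14;NALL=3;COMPLEX	GT:GQ:GL	0/0:10000:0.0000,-71.1575,-285.5492
chr1	5392	chr1:5392:A>G	A	G	.	PASS	BUBBLE=15;NALL=3;COMPLEX	GT:GQ:GL	0/0:10000:0.0000,-92.0585,-188.7002
chr1	5395	chr1:5395:C>CCCATTCATTCCCCTAAACGGAGACCATTGTCATCATAATGTTTTG	C	CCCATTCATTCCCCTAAACGGAGACCATTGTCATCATAATGTTTTG	.	PASS	BUBBLE=15;NALL=3;COMPLEX	GT:GQ:GL	0/0:10000:0.0000,-228.5350,-300.0000
chr1	5529	chr1:5529:T>G	T	G	.	PASS	BUBBLE=16;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-90.6503,-185.8838
chr1	7968	chr1:7968:TCAAACTAACTATTCAGTTGACCATGCCTTACCT>T	TCAAACTAACTATTCAGTTGACCATGCCTTACCT	T	.	PASS	BUBBLE=17;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-56.4275,-300.0000
chr1	8091	chr1:8091:A>G	A	G	.	PASS	BUBBLE=18;NALL=3;COMPLEX	GT:GQ:GL	0/0:10000:0.0000,-173.5752,-300.0000
chr1	8091	chr1:8091:A>T	A	T	.	PASS	BUBBLE=18;NALL=3;COMPLEX	GT:GQ:GL	1/1:10000:-300.0000,-108.4402,0.0000
chr1	8098	chr1:8098:A>T	A	T	.	PASS	BUBBLE=18;NALL=3;COMPLEX	GT:GQ:GL	1/1:10000:-300.0000,-108.4402,0.0000
chr1	8137	chr1:8137:T>TCCTTACCTGCAGTACATGTCTCATTATAACACATTCGATACCTTTATAAATCTCATTTAAGTTCCTGGCATT	T	TCCTTACCTGCAGTACATGTCTCATTATAACACATTCGATACCTTTATAAATCTCATTTAAGTTCCTGGCATT	.	PASS	BUBBLE=19;NALL=2	GT:GQ:GL	0/0:25:-0.0013,-2.5131,-5.7509
chr1	8290	chr1:8290:G>C	G	C	.	PASS	BUBBLE=20;NALL=2	GT:GQ:GL	1/1:10000:-215.8016,-30.6567,0.0000
chr1	9075	chr1:9075:CGGCTAAATAATG>C	CGGCTAAATAATG	C	.	PASS	BUBBLE=21;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-180.9305,0.0000
chr1	9941	chr1:9941:G>A	G	A	.	PASS	BUBBLE=22;NALL=2	GT:GQ:GL	1/1:10000:-300.0000,-135.2567,0.0000
chr1	10697	chr1:10697:G>C	G	C	.	PASS	BUBBLE=23;NALL=2	GT:GQ:GL	0/1:10000:-201.0576,0.0000,-58.8246
chr1	10774	chr1:10774:G>A	G	A	.	PASS	BUBBLE=24;NALL=2	GT:GQ:GL	0/1:10000:-112.2575,0.0000,-167.0893
chr1	11420	chr1:11420:C>A	C	A	.	PASS	BUBBLE=25;NALL=2	GT:GQ:GL	0/0:10000:0.0000,-141.0690,-300.0000
chr1	11584	chr1:11584:A>G	A	G	.	PASS	BUBBLE=26;NALL=2	GT:GQ:GL	0/1:10000:-153.8444,0.0000,-113.1800
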