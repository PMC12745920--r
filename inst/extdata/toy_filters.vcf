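##fileformat=VCFv4.2
##fileDate=20260101
##source=refugia-toy-fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	a1	a2	a3	b1	b2	b3
loc01	10	.	A	T	.	PASS	.	GT:DP:GQ	0/0:30:99	0/1:30:99	1/1:30:99	0/0:30:99	0/1:30:99	0/0:30:99
loc01	20	.	A	T	.	PASS	.	GT:DP:GQ	0/0:30:99	0/0:30:99	0/1:30:99	0/0:30:99	0/0:30:99	0/1:30:99
loc02	5	.	A	T	.	PASS	.	GT:DP:GQ	0/1:9:99	0/0:30:99	0/1:30:99	0/0:30:99	0/0:30:99	1/1:30:99
loc03	7	.	A	T	.	PASS	.	GT:DP:GQ	0/1:8:99	0/0:8:99	0/0:30:99	0/1:30:99	0/0:30:99	0/0:30:99
loc04	3	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:19	0/1:30:19	0/0:30:19	0/0:30:19	0/1:30:19	0/0:30:19
loc05	12	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/1:30:99	0/1:30:99	0/1:30:99	0/1:30:99	0/0:30:99
loc06	9	.	A	T	.	PASS	.	GT:DP:GQ	0/0:10:99	0/1:50:99	0/0:30:99	0/0:30:99	1/1:30:99	0/0:30:99
loc07	2	.	A	T	.	PASS	.	GT:DP:GQ	0/1:51:99	0/0:30:99	0/0:30:99	0/0:30:99	0/0:30:99	1/1:30:99
loc08	4	.	A	T	.	PASS	.	GT:DP:GQ	./.:30:99	./.:30:99	0/1:30:99	0/0:30:99	0/0:30:99	0/1:30:99
loc09	6	.	A	T	.	PASS	.	GT:DP:GQ	0/0:30:20	0/1:30:20	0/1:30:20	0/0:30:20	0/0:30:20	0/0:30:20
loc10	8	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/1:30:99	0/1:30:99	0/1:30:99	0/0:30:99	1/1:30:99
loc11	1	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/1:30:99	0/1:30:99	0/0:30:99	0/0:30:99	0/0:30:99
loc12	5	.	A	T	.	PASS	.	GT:DP:GQ	0/1:9:99	0/1:30:19	0/0:30:99	0/0:30:99	0/1:30:99	0/0:30:99
loc13	3	.	A	T	.	PASS	.	GT:DP:GQ	0/0:30:99	0/0:30:99	0/0:30:99	0/0:30:99	0/0:30:99	0/0:30:99
loc13	9	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/0:30:99	0/0:30:99	0/1:30:99	0/0:30:99	0/0:30:99
loc14	2	.	A	T	.	PASS	.	GT:DP:GQ	1/1:30:99	1/1:30:99	1/1:30:99	1/1:30:99	1/1:30:99	1/1:30:99
loc15	6	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/1:30:99	0/1:30:99	0/1:30:99	0/0:30:99	./.:30:99
loc16	4	.	A	T	.	PASS	.	GT:DP:GQ	0/0:10:20	0/0:50:99	0/1:30:25	0/0:30:99	0/0:30:99	0/0:30:99
loc17	7	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/1:30:99	0/1:30:99	1/1:30:99	0/0:30:99	0/0:30:99
loc18	5	.	A	T	.	PASS	.	GT:DP:GQ	0/1:30:99	0/1:30:99	0/0:30:99	0/1:30:99	0/0:30:99	0/0:100:99
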