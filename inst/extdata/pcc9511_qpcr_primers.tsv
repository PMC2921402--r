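locus_tag	gene	forward_primer	reverse_primer
RNA_42	rnpB	AAGTCCGGGCTCCCATATG	TGTGGCACTATCCTCACGGTTA
PMM0285	phrA	GGAGAGACCGGAGTACCTATAGTTGA	GCGACTATCATCCTACATCTATTATGCA
PMM0395	sepF	GAAAGAGTCGGTGAAAGCATTTTT	GCCTCCTCTGGGAAAGAACTAGT
PMM0565	dnaA	TGGTGTCGGTCTTGGAAAGAC	CTTTCGCATCTGGATCAATTTCT
PMM0937	umuC	TCAAGTAAGTAGAAGCTTTGGAAAACC	TAGTAATGGCAGATGATTTTAAGCTTTG
PMM1054	ruvC	GCAGGCTCTGGCAAAGCA	TTTGGTGCACGGGTTAAATTT
PMM1077	sasA	CTTTTAAGAATGGTTGCACATGAATT	TTTGTCCTAGTTTTTGACTTTGAATAGC
PMM1262	lexA	AGATCTTTGAGGGAGTCCCAATT	TGGAGGTCGGAAAATGTTTCA
PMM1309	ftsZ	GGGATAGTAACCAAGCCATTTTCA	TCTGCTAATCTTGCAATCCCTTCT
PMM1342	kaiC	AGGAACCGTACATATGAAAGGAGAA	CTCATCGCTCCTAAGGCAAAA
PMM1343	kaiB	AAACAACCTCAACTTGCTGAAGAA	TAACAGGAGGAGGTAAAATCTTTGC
PMM1452	atpD	AATCGACCCATCCCTCATTG	ATTTGAGAGGCAAGACTAGCATCA
PMM1455	atpH	GCCCGGGCCTTGGA	AGGTTGGCGGGCAATACC
PMM1562	recA	GCTGAACATGCTTTAGATCCAGTCT	GTATCTGGCTGCGAAACTAGTAAATTT
PMM1629	rpoD8	CAAAGCTGGGCAGCCAGTA	CAGTCCATTTCGATTTGCTCATC
PMM1645	mutS	ACAAGAATTGGAGCCGTAGATGA	TGATTTAGTATTGATGCTGTTTCTGACA
PMM1697	rpoD4	CTCAAAGTGCTCCATGCGC	GATTGTTCTATCCATCCCTTCCA
PMM1712	uvrA	GATAATTGATCTTGGACCTGATGGA	ACTTATTGGATGCTTCGCAACA
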