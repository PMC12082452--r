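id	sequence	type	panel	target
TBA	GGTTGGTGTGGTTGG	DNA	reference	Thrombin
Apt8	TGGTAGGAGGTGCGAAATTGGGGGGGTGGGGTAGCGGT	DNA	g_rich_high	CDP-ribitol synth.
Apt22	CGGGAAGAGGGTAAGGGGAGGGAGGGT	DNA	g_rich_high	A85A prot.
Apt51	CGGGCAGGGGTGGGGGGGTGTTTGCGGCTCTGGGA	DNA	g_rich_high	IL2Ra
Apta14	TGGGCGGGGAGTAGGGAGAGGGGT	DNA	g_rich_high	HPV
Apt2	CGGTGCAGGGGGGGCGGAGAAGAGGTTGAGGGGAGCGGGT	DNA	g_rich_high	Alloantibody
Chi46	CGGGGGGGGGAGAAGGCAATGGGGGA	DNA	g_rich_high	Chitin
E1	TGGCGGTGGGTGGGGGACAAATTTGGGGGGCGTTGGGT	DNA	g_rich_high	HepG2
F1	TGGGTGGTGGGGAGGGGGTTGCTGGGT	DNA	g_rich_high	HepG2
FKNS2	CGGGGTGGGTGGGGGGCACGTGTGGGGGCGGCCAGGGT	DNA	g_rich_high	Fractalkine
QA12	TGGGTAAGGTCTGGTGGATTGTGGACGGGGGGCGGGGCA	DNA	g_rich_high	Iridovirus
RNVL7	CGGCGGGTGGGCGGGGGGAGAACGAGGTAGGGGT	DNA	g_rich_high	LDLR
T24	CGGGCGGGGGTGCTGGGGGAATGGAGT	DNA	g_rich_high	Tetracyclines
0913	GTGTACGGGGTCCGGTAGGGTGGCG	DNA	g_rich_low	NA
0469	CCTGCAAGCGGGAAGAGGGCAGGGGTGGGAGGGTAACGCGGAAAGGGCA	DNA	g_rich_low	NA
0053	GTAACCTGTTGGGAGGGCGGGTAGGG	DNA	g_rich_low	NA
0058	CGGGACGGGTGGGTAAAAGGTGT	DNA	g_rich_low	NA
0560	AGGGCTTGGGTTGGGAATAAGGATGTGGGAGGCGG	DNA	g_rich_low	NA
0143	CCATCTGTGTAAGGGGTAAGGGGTGGGGGTGGGTACGTCT	DNA	g_rich_low	NA
0600	TAGGTGGGTGGGGGACACTGCCCGGGGGTGGTTGGGT	DNA	g_rich_mid	NA
0200	ATGGGGTCGGGCGGGCCGGGTGTC	DNA	g_rich_mid	NA
0646	CTAGGTGGGTGGGGGACACTATCCGGGGGTGGTTGGGTG	DNA	g_rich_mid	NA
0060	TGGGCGGAGGGCTAACGGTGGGGGGATATTATGAGGGGTGGAGGT	DNA	g_rich_mid	NA
0478	CGGCGATGGGGTAGGGGGTGTGGAGGGGCCGGACGGAGGGGCAGCAAGGC	DNA	g_rich_mid	NA
0672	AGGTGGGTGGGGGACACTACTCGGGGGTGGTTGGGTGA	DNA	g_rich_mid	NA
0902	GGGAUGAGGGACGUGGGAAUCUUGG	RNA	rna	NA
1248	GGAAGGAGGGGCAUGCGGUCCAGGG	RNA	rna	NA
0898	GGGACCGUGCGAGGGUUGGGUUAGGG	RNA	rna	NA
1052	CGGGGGCGUUUCGGCGGAGGAGUGGGA	RNA	rna	NA
0861	UGGGGUGUCGGGCGAUUUUUAGGGUUGGG	RNA	rna	NA
0192	GGAGAGGGUGGGUGUGCGUGGCGUGGGGU	RNA	rna	NA
PL1	CCCCCTCCTCCCTCCCCCACCCGACACTATTCCCCCCCACACC	DNA	c_rich	Protein L
PL2	CCCTCCCCCACCCGACACTATTCCCCCCC	DNA	c_rich	Protein L
PL3	CCCCCTCCTCCCTCCCCCACCC	DNA	c_rich	Protein L
BB1	CCCACCTCGTGATCCCCTTCCCCC	DNA	c_rich	NA
BB1	CCTCCCTCCTCATATCCCTGCCCC	DNA	c_rich	NA
BB1	CCCGCCCCGCTCCATCCGCCC	DNA	c_rich	NA
BI1	CCCACCCACCAGCCCCAACATCATGCCC	DNA	c_rich	NA
AN1	CCCTAACAACCAGCCCACCCACCACCCC	DNA	c_rich	NA
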