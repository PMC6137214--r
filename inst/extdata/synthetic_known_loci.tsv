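locus_id	unit	n_units	upstream_flank	downstream_flank
HK01	CTTT	12	TGTAGCGCATATGCGCCAAGGCCAG	AAAATCGACGTCAAGTCGGTCCGAC
HK02	CTTT	16	ATGGCTGCGCATATGGGACTGAAGA	CAGCCCCCATTGACGACGAGAATAC
HK03	CTTT	18	TCGAGCGTCGCACATATGCGTGGCA	ATTGACGACAAGATGCAGAATCGTC
HK04	CTTT	16	CATGATCGGCGCATTTGCTGGAACT	CAAGTTGACGTCAAGACGTAATCGC
HK05	CTTT	15	CAACAACGCGCATATGCGATGAGAG	GCTCAGGGGCTTGACGTCAAGGGCA
HK06	CTTT	21	CATAAGGGGCGCATATGCGCACCCG	AGTACTTTGACGTCATGACGCCACG
HK07	CTTT	15	GCATTTCGGCTGCGGATATGTGCCG	TTTGACGTGCAGTGCGCCTTAGCCG
HK08	CTTT	17	GGCAGCGCATATGCGACCAGGATTG	TGAGATATGTTGACGCCAAGGACAC
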