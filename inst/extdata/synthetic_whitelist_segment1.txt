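ACGCATGAC
ATCACGCAC
ATTTACAGG
ACAGTAGCA
CAGACGCCC
TACCACTGT
CCAGTCACT
CTAACCATC
ATAGGATGG
TCCCCAGAA
GAGAACGTC
TTCCCACGC
GGGCGGCTC
TACAACCCG
ACGGCTCCT
ACGATTGAT
CCTCCGCAT
TTTCGGTAG
CCTCTCTAG
CGAGCCAAT
GTTAAGACA
GGCGTGCTG
ACTATAGGG
AAAGTTGAC
GTTTGCGGC
TCGTCATTA
AACCAAGTG
GCACTGCAG
AAGTCCAGG
TATTTGCTC
CGATCGGCC
TCAATAGGT
TCTGCTCAG
GTATCGAGG
CCTTAACAG
AACTCGATC
CACTTAGAT
TGTGGGCGA
CCTGCGCTA
GCATCCTTA
GGGTCACGC
CGTACCGGA
CAAGGTTAC
TGGGATGTG
TTTCTACGG
TCCAGCATC
CTGCTTGCC
CAAGCTCGT
AGCGTTCCT
TGCAGCCAC
ACCACCTCC
TTCCTCCTC
CTTGACAAG
TTGCTGCGA
GAGAGTAGT
TAATAAAGG
GATCCCTGC
ACGGGGTAC
AAAAGATAA
CTGGTCGGA
CGGCCTCCA
CATGATCCC
TACTCTAAT
GTAACGTTC
CATATCCAG
AACGGAAGT
CAACACGGT
GTGGTATAT
CCGCGAGCC
CGCCTAACG
CTGAGTTGC
TGGAGTTAC
ATCCACCTT
AGACGTAAT
AATCCAGCA
GACGGCTAA
TTCCACAGA
AAGAGGTAG
CCATGCTCT
AGCTGAGAC
ATGTTTTGC
TGCAATTTA
TAACCGTTA
GTCAGTAAC
GCAAACCAG
AGAGTGCTT
TTCTATGGA
ACGAGGCGA
TGGCAGACA
TGCCTAGGG
CATCATTGA
AACATTTAA
CGTCCCCGC
CCAGGTCCG
CACTAAGCA
TGAACGTCC
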