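ATGAGTATT
AGGAACATC
TAAGGTCTC
GGCTGTAGA
TGATCAGCA
TCTACCGTA
GGTTAACTA
TTTTTGCAC
GAGACGTAA
ATCTAGCTG
AAGTAAGCC
AGGACATCA
AACAGGTCC
AACTAACGT
CAGCTGACG
GCCTCAACT
GTCTGGAAA
ATGTTAGAT
TACCGGCGT
AGTTCTCTT
GCCCGCGAG
GGACGTAAA
CCTATTAAC
TCGGGCTTG
GGCGTCCAC
GTTTGTAGC
GACTGTACG
TGGGAACCC
CCAGACTCT
AATCTTTAA
AGATCCGGT
CATACGGTG
AGGCCAACG
GGAGAGAGC
AAACGAGGC
TATTACTAC
ATAAGCCCT
TCACACTGC
GAGCGACCG
TGTGGTAGT
GGTTGACGG
TACTTGACG
GGACATGTG
GAGGGAGTT
TGTGGCTCG
AGGCATTCA
GCGAGACGC
AGAACGTTT
TGTCTAGAG
TTAAATCGC
AACTATTAT
CACAATGTG
CAATGCCAG
GATTCGAAG
GCCGTGGCT
CTGCGGGCT
AAATTCCGA
GATGTATAG
CGCCGAGAC
TTAAAAGCT
CGGAGGGTA
TTGGGATAG
TGGAGAGTC
TAATTGCTC
TAAAAACCG
CTCTGGCAG
GTCTCGTCA
GATTTAATA
TAAAGCCAC
GAGGACATA
GAGGCACCA
GTCTACACC
TGCGGTCAT
GCAGTAGAC
CGGCGACAT
CGCTTTTTT
CCGGGAAGA
GGGGATATG
GCAAGTGGC
CATCCTAGG
GGATGGCCT
ATTTCAACT
CTCGGCATG
CTAGAGAAA
CGCGAGGAG
ATATGTCAC
AATATCTGG
AGCGCCTCG
CACTGAGTG
TCCGTACTC
CTTGGTGGT
GCGCTCCAC
GATCCTCTA
ATGGTCATG
TAGATAACA
AGCCCTATG
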