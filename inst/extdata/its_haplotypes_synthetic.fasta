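>HapA synthetic ITS1-5.8S-ITS2 amplicon, haplotype A (C at 241, TGC at 465-467)
GGAAGTAAAAGTCGTAACAAGGCGCACTTTGAGTTCACGCATCCAGAGTGCCAGTCGCCC
TTATGACCGGTCGCGTACTCTTTTGGTGGTATGACTAGCATCCGATCATGTACGGTTTCT
ACTGCGGAACAGTCTTGCTAAGCTTGGCCCTAAGGAAGTACTGAGCCCGGACACGGGCCA
TTACTAAAACCTACCAAATTACTAGGGTATTCTCCCTTAAACCGTACACAGGACGAGTCG
CCGGCTGCCAGCAATGTGGAACATTTGGATTCACCAATAAAACTTGATACAAACTTACAG
TTTGCGATTGTCGCAAACGCGTGCATCATTCACATTCCTAACACCGTAGCGCCCTGAACA
GTGGGGCGTCCGTGCTCACACATGTGGTTGTAGCCGCCTACGGTCACCAGAGTTTGTTTA
GCTCTCAAACTTTCACATTTACCTAGGGACCACTACTATTCGGATGCGTTTAGGCCAGTC
TTGTCGGCGCAACCCGTTGCCGCGCAGAAATTCGGGCAGGCCTAGTTCGTGCAACAGCAG
AGCGACTCGTTCCCTAGCGATTGGGACCGAGGGTTTCGCAAGGTGCCGTACTACGAAGCG
GACATGTACTGAAAAACCTCCCAACATTGACGTCCATGTGGTTTTAACGGTCGAAAAGGA
GCCTTAGTGACCCTCAATCTTCCATGTTTTAGTAATTGCCCCTCCTCAAGCATATCAATA
AGCGGAGGA
>HapB synthetic ITS1-5.8S-ITS2 amplicon, haplotype B (T at 241, CAA at 465-467)
GGAAGTAAAAGTCGTAACAAGGCGCACTTTGAGTTCACGCATCCAGAGTGCCAGTCGCCC
TTATGACCGGTCGCGTACTCTTTTGGTGGTATGACTAGCATCCGATCATGTACGGTTTCT
ACTGCGGAACAGTCTTGCTAAGCTTGGCCCTAAGGAAGTACTGAGCCCGGACACGGGCCA
TTACTAAAACCTACCAAATTACTAGGGTATTCTCCCTTAAACCGTACACAGGACGAGTCG
TCGGCTGCCAGCAATGTGGAACATTTGGATTCACCAATAAAACTTGATACAAACTTACAG
TTTGCGATTGTCGCAAACGCGTGCATCATTCACATTCCTAACACCGTAGCGCCCTGAACA
GTGGGGCGTCCGTGCTCACACATGTGGTTGTAGCCGCCTACGGTCACCAGAGTTTGTTTA
GCTCTCAAACTTTCACATTTACCTAGGGACCACTACTATTCGGACAAGTTTAGGCCAGTC
TTGTCGGCGCAACCCGTTGCCGCGCAGAAATTCGGGCAGGCCTAGTTCGTGCAACAGCAG
AGCGACTCGTTCCCTAGCGATTGGGACCGAGGGTTTCGCAAGGTGCCGTACTACGAAGCG
GACATGTACTGAAAAACCTCCCAACATTGACGTCCATGTGGTTTTAACGGTCGAAAAGGA
GCCTTAGTGACCCTCAATCTTCCATGTTTTAGTAATTGCCCCTCCTCAAGCATATCAATA
AGCGGAGGA
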