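>rluc_synthetic synthetic 312-codon CDS at the scale of the Renilla luciferase ORF
ATGAGGCTCTTCCCTACAATGTTGGGCATCCTGCGGGCCTTCGATTCCTCCACTCTTAGG
CGCGACTGCTTGAGAGCTGAGTATCGACTGCGACATGCGGCGAGAGCTAACCACTTTGCT
TTGGTGCCTTACTGTCGTATGCGGTGCACTAAGCGATCGTCTCCATCGCGCCGATCCATG
CAATCACCGCGCGAATCGGATCATCAGCGAAATTCACGGACCCGATGTCCGACAGTCGTA
AGTGGTATACCTTCCCCCATCGGTGCCGCGATTTACGATCGGGGCACAGGTTCACGCCAG
GAGAGCTTCTCAAATGGTGACCTAATCCGTATGCTGTTCCTCTCATTCCATCCCACCCGG
CCTTTCTCATTTGGTCTCCAGACTAGACCGCCGGTGTCATATGCCGTCTTACTTCCCAGC
TGTTCAAGAGAGACGATGCATCCCTTTGCTCTTTGCAGCGAAAGCGGGAGGCCGTACTGC
ACGAAAGATCTGACGGGACAAAACTCCGACGCGCATTACATTTCTTCTGGATTCCATTCC
TGTGTCTCACTATTTTGCTCAGTAAGACACCGCGCGGCGACCCTCTTTGGTGGTTTCAAG
TCCGAGGTTGCGTTGTATGCATATGCGAATAAGTGGGGGATCCCAACTGTATCGCGAGCA
GTCCAAGTTCCCGATGTACGCAGAGTCGCATGTTCACTATTGGAGGATGATTGCACGGAC
GCTTCCCTCTGTGCAGCCCGAGCCAATTTCCTATGTATCTCATTTTCCATGTCCATCGTT
CGATCGGATGCAAGCGGATTAGAGTGTACAACCTCTCCGAGCTTGTGTCATTGTCTCTCG
GGGTTTAGGAATCTGGGATCGAAGTGTGCTTTTAATATTGAGGTCGCCAATGGTCGTGTC
CCGACGGCAACGCCTGGTTCTTCGGCTTGCATCTAA
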