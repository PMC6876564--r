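>primer5
GCCTATAATGCTGGCGCAAGGGATC
>primer3
CCGGTGGACAAATTAGGTGGCGAG
>body
CCACTCATCAATCACGCCGACTCGGGGTACCAACAACCTAGCGAGCCAGAATGTTACTGGATTAATAACCGTACGTTGGATACTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCATCCAAAAATGAGCATATCTTCTTCTTAAGTAAAAGGTCGGCAAACGTTGTAAGTATGTTTAGTGGGTACTTTCTGGCTCCCTTACGTTGGGTCCACGCCCTACGACTTTCATATTCCCGCAGGTCCCTGCGGCCTTCTACAATTGGGGTCTCAGCAGTAAGCCTGTCTAGGCGAATAACTGGGTCCCGAGCGAGTGTGGTAATGCGTTATGGCTCCCTAAATATCGGAGACACGCCCTTTATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGAGTTATGCCACCATTCAGTATCGAATCAGCTCGCAAGATTGTTATGGGGCCATTAAGCTCGCTGAATTCACGTCGCCGTATCGGTCGTTGAGCCGCTTATTCCGGTTGGCCGCCCAGTAAAATCAAACCCTGCTAGTCAGCCGGATGCTGATACTCACTAAGCAAGCTTACATCCGGTAGTACCACAAACGCTGCGCGTTTCCCG
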