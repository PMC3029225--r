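>rnr1_amplicon_synthetic rCRS-like synthetic amplicon, positions 618-2007 (1-based)
CGGAGACATAGAAACGAGAACGCTAGGGGGGGACCGGTTTACCGGAATTAGAGTGTCCCTTAGTAGAAAT
GCCTCAATACAATTGGACGCTGGGGGCCTTGAGAGAACTATCTGCCGATAGTATGGCGGAAGGCCGTTGT
GTATATATTGAAGGTTTCGCACGAATCAACCTTTGATGCCGGAAGCTGTCCGTATACGCCGCCTATCGGA
GAGTACGCCCAATAAACAAGGCCTCGATGTTTGATCCCACGAGCTCGTACCGGTGTGTACGTAATCCTGC
GATTGTTGTAACAAAAGTTCAGATCTTGTATAAAAATTGCCTCGAAGTGAAGGGATCAACCCCTTGACTT
ATATAGGCAAGGTGCGCGCACGTCTCCTAATAGGATCTAACCATACGTAGCAGAGTGGTAAGGTACACCA
AGAATACAACCCCTGGCGCGGTGTAATGGCCCCTGGAGGGACACCGGGCACGTCACCTACGATAGATACT
ATATTTTATTTTCCCAAGTTTGTCAAACTGGCTATGGCTTTGTTTCTCCCGCTTCGGGGATTGACTCTGC
CGTGAGTAGTTTTCCGTGTAGATAGAAGCCGTCCTGCGACTTCTAGTTTCCCGCGATATCCGGCGAACTG
GGGCTTGCACTGAACTTTGGATCCTGAATGGCCCGGTCCCTCTAAATGATTCAAGCGCTATACCGCATGT
TACCTCTTATGCGATCACACCAGGCGTGGTATGGCAGATTGGGGAAGCCATGCGACCCACCCCCAATCTC
CCTTGGTCGCAGTTAGGTGTAACGATTCAGCAGCGGAAATGGGATGTCTTGATTGGACGATTCTTGGCCG
GCGTGATCACTGGCGGTACCCCCAGCCGTCTTCGTTCGAAATACTGTCATCCGCCGGCTCACCGATTGCT
CTTTCAAAAGAACTGTCCGACTTGTCGAGAAGTAGTCGTACGACTCCTTCGGCCGGTATTCACGTCCCAA
GCGGGACTTGCGTGACAACTGACGGGGGGGGTACAACGTATCCAACGGAAGTATACCCAGTGCGACTTCA
TCTGGTCGCACACCAGGGGGTGCAGACTCTTAGCTTCGTTAGCACTCATAATGAACTCACCCAGTACGAC
CGGGCGGTAATCGCAGAAACGATTCCCAGAGGCACGGGAGCCACAGCGAATCCTCTTACCATTTTCAAAA
CGTGAGCTAGCGTACCTAATTGGACACGAGTCTCCCTAACGTTGGCCCGAGAGGGCATTCAACGTTCCCC
CAAAAGACAATATCTTCGTACCGCGGAACACACGGGCATCTTCTCATTATAACGTACTGTATGCCGTATC
GGAGCTTTCTGCCGATTTGATGACCTCGTTGTCGTGTCTTACGACAGTTCCTGGCACGAG
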