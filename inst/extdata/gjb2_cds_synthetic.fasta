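>GJB2_CDS_synthetic synthetic stand-in coding sequence, cDNA coordinates 1-678
ATGTCCGTCCTCATTAGTCAGAGAATTCCTGGATCACCTTCTTCTGCCACCTATAGTCGCCGTGCCTATC
CACAAACGAGAGGATATAATCCGAATAGCAATGATGTTCATAAGAGCGAGACGAGCTCAGCGGAGCGCAA
TATACCATTGGGTCCCCGTAAGCTCGGCGACGAGTGCGCGGCTGGTTCGGGCTTTCCGCTTTTCCGACCT
TTTAGAAGGAGATAGCTGCAGTGACGCGACTGGTATATGCCATCCTACGCCAACTTCGCCCTATCGTCTT
TACGTCCTATAGTATCTGATCGAGCGAGTAACTCGCCCAGTTAATCTACACTGCTACGAGTGCGATCTCC
GTCACACAAGGATTAGTCTGGGATAGAGGCGAGCGGGGAAATGCGTGTTGAGTCGTGCTAGCAAAAATGA
CCGACGATATGCGACATGCATTCGCTGAATCTGGCCCCTCTACCGATTTCCCCAAATTAGCTATCACTCC
GAGTATAACACACATGCATAAACGCGACCCTACTTGTGCGTTGAGCCATGCGAAGCGCTTTCGTCTCAAG
CAGGTTAACAGGCTCCCAGTTGGCACCGGGCTGTAGCTGATGAGGGTAATTGACTCTAGACTACTTTGTT
TTTTTGAATAATCTATGCATTGTGCCTAGTATTCTGAACGGTACCTAA
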