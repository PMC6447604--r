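>gblock_LINE1_60 synthetic quantification standard carrying the 60-bp LINE-1 amplicon
ACTGTGAACTAGTTCAACCATTGTGGAAGACAGTGTGGCGATTCCTGAGGGATCTAGAAT
TCGAAATACCATTTGACCCAGCCATCCCATTACTGGGTATATACCCAAAGGATTATAAAT
CATGC
>gblock_ND5_83 synthetic quantification standard carrying the 83-bp ND5 amplicon
TCTAGGCCTTCTTACGAGCCAAAACCTGCCCCTACTCCTCCTAGACCTAACCTGACTAGA
AAAGCTATTACCTAAAAGAATTCCACAGCACCAAATCTCCACCTCCATCATCACCTCAAC
CCAAAAAGGCATAATTAAACTTTACTTCCTCTCTTTCTTCTTCCCACTCATCCTAACCCT
ACTCCTAATCACATAA
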